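edge_vis <- function(spsd, source, rf) {
  e <- spsd$edges
  e$visibility[e$source == source & e$rf == rf]
}

test_that("SPSD topology follows the perturbation regime", {
  for (k in 2:3) {
    sp <- enumerate_search_space(k)
    set.seed(k)
    for (b in sample(sp$indices, 5)) {
      f <- decode_index(b, k)
      d_do <- build_spsd(f, "DO", "TX")
      expect_equal(nrow(d_do$edges), k * 2^k)
      d_d <- build_spsd(f, "D", "TX")
      expect_equal(nrow(d_d$edges), k / 2 * 2^k)
      for (s in 0:(2^k - 1)) {
        out_d <- d_d$edges[d_d$edges$source == s, ]
        expect_equal(nrow(out_d), sum(oracle_bit(s, 1:k, k)))
        expect_true(all(out_d$kind == "D"))
        expect_true(all(out_d$dest < s))
        out_do <- d_do$edges[d_do$edges$source == s, ]
        expect_equal(nrow(out_do), k)
        expect_true(all((out_do$kind == "D") == (out_do$dest < s)))
        expect_equal(sort(bitwXor(s, 2^(k - out_do$rf))), sort(out_do$dest))
      }
    }
  }
})

test_that("R1 visibility of F_11^2 matches the worked two-input diagram", {
  d <- build_spsd(decode_index(11, 2), "DO", "TX")
  expect_equal(edge_vis(d, 1, 1), "R1_VISIBLE")   # O1: 1 -> 3
  expect_equal(edge_vis(d, 3, 2), "INVISIBLE")    # D2: 3 -> 2
  expect_equal(edge_vis(d, 2, 1), "INVISIBLE")
  expect_equal(edge_vis(d, 2, 2), "INVISIBLE")
  expect_equal(sum(d$edges$visibility == "INVISIBLE"), 4)
})

test_that("half the edges of NOT(RF1) AND RF2 are invisible under DO/TX", {
  d <- build_spsd(decode_index(4, 2), "DO", "TX")
  expect_equal(nrow(d$edges), 8)
  expect_equal(sum(d$edges$visibility == "INVISIBLE"), 4)
})

test_that("PPI upgrades require a present, R1-visible co-regulator", {
  d <- build_spsd(decode_index(4, 2), "DO", "TX_PPI")
  # D2 out of 11: D1 out of 11 is visible and both bits are 1 -> upgraded
  expect_equal(edge_vis(d, 3, 2), "PPI_VISIBLE")
  # O2 out of 10: no visible anchor at the source -> stays invisible
  expect_equal(edge_vis(d, 2, 2), "INVISIBLE")
  # upgrades never downgrade anything
  tx <- build_spsd(decode_index(4, 2), "DO", "TX")
  was_visible <- tx$edges$visibility != "INVISIBLE"
  expect_true(all(d$edges$visibility[was_visible] != "INVISIBLE"))
})

test_that("top-state knock-down edges all upgrade iff one is R1-visible", {
  for (k in 2:3) {
    top <- 2^k - 1
    sp <- enumerate_search_space(k)
    for (b in sp$indices) {
      d <- build_spsd(decode_index(b, k), "D", "TX_PPI")
      out <- d$edges[d$edges$source == top, ]
      any_r1 <- any(out$visibility == "R1_VISIBLE")
      expect_equal(all(out$visibility != "INVISIBLE"), any_r1,
                   info = sprintf("k=%d b=%d", k, b))
    }
  }
})

test_that("cis+PPI integration makes everything visible", {
  set.seed(3)
  for (k in 2:3) {
    for (b in sample(enumerate_search_space(k)$indices, 6)) {
      d <- build_spsd(decode_index(b, k), "DO", "TX_CIS_PPI")
      expect_true(all(d$edges$visibility != "INVISIBLE"))
      expect_true(all(d$fully_visible))
      dd <- build_spsd(decode_index(b, k), "D", "TX_CIS_PPI")
      expect_true(all(dd$fully_visible))  # states gated even without k edges
    }
  }
})

test_that("DO/TX visibility is symmetric across reciprocal edges", {
  for (k in 2:3) {
    for (b in enumerate_search_space(k)$indices) {
      e <- build_spsd(decode_index(b, k), "DO", "TX")$edges
      key <- paste(pmin(e$source, e$dest), pmax(e$source, e$dest))
      for (pair in unique(key)) {
        vis <- e$visibility[key == pair]
        expect_length(vis, 2)
        expect_length(unique(vis), 1)
      }
    }
  }
})

test_that("exports carry the diagram faithfully", {
  d <- build_spsd(decode_index(11, 2), "DO", "TX")
  dot <- export_spsd(d, "dot")
  expect_equal(length(gregexpr("->", dot)[[1]]), 8)
  expect_equal(length(gregexpr("style=dashed", dot)[[1]]), 4)
  expect_identical(dot, export_spsd(d, "dot"))  # byte-stable

  gml <- export_spsd(build_spsd(decode_index(22, 3), "DO", "TX"), "graphml")
  expect_equal(length(gregexpr("<node ", gml)[[1]]), 8)
  expect_equal(length(gregexpr("<edge ", gml)[[1]]), 24)

  js <- export_spsd(d, "json")
  back <- spsd_from_json(js)
  expect_equal(back$edges, d$edges)
  expect_equal(back$fn$b, d$fn$b)
  expect_error(export_spsd(d, "svg"), "unknown export format")
})
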