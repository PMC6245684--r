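test_that("observation sets validate, merge and reject conflicts", {
  o <- observation_set(2, c(3, 1), c(1, 0))
  expect_equal(names(o$observed), c("1", "3"))
  expect_error(observation_set(2, c(1, 1), c(0, 1)), "conflicting")
  expect_error(observation_set(2, 4, 1), "state numbers")
  m <- merge_observations(o, observation_set(2, c(1, 0), c(0, 1)))
  expect_equal(unname(m$observed), c(1L, 0L, 1L))
  expect_error(merge_observations(o, observation_set(2, 1, 1)), "conflicting")
  expect_error(merge_observations(o, observation_set(3, 1, 1)), "different k")
})

test_that("observations_from_step records the step's transitions", {
  f22 <- decode_index(22, 3)
  st <- observations_from_step(f22, 3, "DO", first_step = TRUE, integration = "TX")
  expect_equal(st$observations$observed, c(`1` = 0L, `2` = 0L, `3` = 1L, `7` = 0L))
  expect_setequal(st$destinations, c(7, 1, 2))
  expect_true(st$fully_visible)
  expect_equal(st$n_visible, 3L)

  st2 <- observations_from_step(f22, 2, "DO", first_step = FALSE)
  expect_equal(st2$observations$observed, c(`0` = 0L, `2` = 0L, `3` = 1L, `6` = 1L))

  st0 <- observations_from_step(f22, 0, "D", first_step = FALSE)
  expect_equal(st0$observations$observed, c(`0` = 0L))
  expect_length(st0$destinations, 0)
})

test_that("the F_22^3 two-step worked example counts 16 then 4", {
  f22 <- decode_index(22, 3)
  o1 <- observations_from_step(f22, 3, "DO")$observations
  r1 <- consistent_count(o1, indices = TRUE)
  expect_equal(r1$count, 16)
  expect_equal(r1$indices,
               c(16, 18, 20, 22, 24, 26, 28, 30, 144, 146, 148, 150, 152, 154, 156, 158))
  o2 <- merge_observations(o1, observations_from_step(f22, 2, "DO", FALSE)$observations)
  r2 <- consistent_count(o2, indices = TRUE)
  expect_equal(r2$count, 4)
  expect_equal(r2$indices, c(18, 22, 26, 30))
})

test_that("consistent_count edge cases and dual routes agree", {
  expect_equal(consistent_count(observation_set(3)), 218)
  full <- observation_set(2, 0:3, decode_index(6, 2)$outputs)
  expect_equal(consistent_count(full), 1)
  # exhaustive dual-route check at k = 2: every possible observation set
  for (mask in 0:15) {
    st <- which(bitwAnd(mask, 2^(0:3)) > 0) - 1L
    for (vals in 0:(2^length(st) - 1)) {
      v <- as.integer(floor(vals / 2^(seq_along(st) - 1)) %% 2)
      obs <- observation_set(2, st, v)
      a <- consistent_count(obs, method = "filter")
      b <- consistent_count(obs, method = "completion")
      expect_identical(a, as.integer(b))
      expect_equal(a, oracle_consistent(st, v, 2))
    }
  }
  # sampled dual-route checks at k = 3 and 4
  set.seed(99)
  for (k in 3:4) {
    for (rep in 1:25) {
      nst <- sample.int(2^k, 1)
      st <- sample(0:(2^k - 1), nst)
      v <- sample(0:1, nst, replace = TRUE)
      obs <- observation_set(k, st, v)
      expect_equal(consistent_count(obs, method = "filter"),
                   as.integer(consistent_count(obs, method = "completion")),
                   info = sprintf("k=%d rep=%d", k, rep))
    }
  }
})

test_that("single-step P_ua reproduces the headline probabilities", {
  expect_equal(unambiguity_probability(2, "DO", "TX_CIS_PPI", 1)$P_ua, 0.8)
  expect_equal(unambiguity_probability(2, "DO", "TX_CIS_PPI", 2)$P_ua, 1)
  expect_equal(unambiguity_probability(3, "DO", "TX_CIS_PPI", 4)$P_ua, 1)
  for (k in 2:3) {
    r <- unambiguity_probability(k, "DO", "TX", 1)$P_ua /
         unambiguity_probability(k, "D", "TX", 1)$P_ua
    expect_equal(r, 2^k)
  }
})

test_that("P_ua is monotone in steps and in integration richness", {
  for (k in 2:3) {
    for (i in c("TX", "TX_PPI", "TX_CIS_PPI")) {
      p_do <- vapply(1:4, function(np)
        unambiguity_probability(k, "DO", i, np)$P_ua, numeric(1))
      expect_true(all(diff(p_do) >= -1e-12))
      p_d <- vapply(1:k, function(np)
        unambiguity_probability(k, "D", i, np)$P_ua, numeric(1))
      expect_true(all(diff(p_d) >= -1e-12))
    }
    for (r in c("D", "DO")) {
      p <- vapply(c("TX", "TX_PPI", "TX_CIS_PPI"), function(i)
        unambiguity_probability(k, r, i, 1)$P_ua, numeric(1))
      expect_true(all(diff(p) >= -1e-12))
    }
  }
})

test_that("DO+cis experiments that cover the diagram leave no ambiguity", {
  res <- unambiguity_probability(2, "DO", "TX_CIS_PPI", 2)
  expect_true(all(res$min_common == 1))
  res3 <- unambiguity_probability(3, "DO", "TX_CIS_PPI", 4)
  expect_true(all(res3$min_common == 1))
})

test_that("knock-down paths exhaust after k steps", {
  expect_error(unambiguity_probability(2, "D", "TX", 3), "state 0 after k")
  expect_error(unambiguity_probability(3, "D", "TX_CIS_PPI", 4), "state 0 after k")
  # within range, descending paths are fine
  expect_s3_class(unambiguity_probability(3, "D", "TX", 3), "ambiguity_result")
})

test_that("mean ambiguity counts average the right sets", {
  # the F_22^3 top... initial state 3 contribution (16) is part of DO/TX mean
  res <- unambiguity_probability(3, "DO", "TX", 1)
  b22 <- which(enumerate_search_space(3)$indices == 22)
  expect_equal(res$min_common[b22, 3 + 1], 16)
  # D averages only the top state
  m_d <- mean_common_count(2, "D", "TX_CIS_PPI")
  top_counts <- unambiguity_probability(2, "D", "TX_CIS_PPI", 1)$min_common[, 4]
  expect_equal(m_d, mean(top_counts))
  for (r in c("D", "DO")) for (i in c("TX", "TX_CIS_PPI"))
    expect_gte(mean_common_count(2, r, i), 1)
  expect_gte(mean_common_count(3, "DO", "TX", fully_visible_only = FALSE),
             mean_common_count(3, "DO", "TX", fully_visible_only = TRUE) * 0 + 1)
})

test_that("ratio tables reproduce the printed k=2/3 comparisons", {
  tb <- ratio_tables(2:3, 4, np_policy = "saturate")
  rr <- tb$regime_ratio
  pick <- function(k, np, i) rr$ratio[rr$k == k & rr$n_p == np & rr$integration == i]
  expect_equal(pick(2, 1, "TX"), 4)
  expect_equal(round(pick(2, 1, "TX_CIS_PPI"), 1), 1.8)
  expect_equal(round(pick(2, 2, "TX_PPI"), 1), 2.5)
  expect_equal(round(pick(3, 2, "TX_CIS_PPI"), 1), 4.3)
  expect_equal(round(pick(3, 3, "TX_CIS_PPI"), 1), 5.7)
  expect_equal(round(pick(3, 4, "TX")), 16)       # DO at 4 vs D saturated at 3
  expect_equal(round(pick(3, 4, "TX_CIS_PPI")), 8)
  expect_true(all(rr$saturated == (rr$n_p > rr$k)))

  ig <- tb$integration_gain
  gd <- function(k, reg, i) ig$mean_ratio[ig$k == k & ig$regime == reg & ig$integration == i]
  expect_equal(round(gd(3, "D", "TX_CIS_PPI")), 18)
  expect_equal(round(gd(3, "DO", "TX_CIS_PPI"), 1), 8.4)

  # feasible policy blanks saturated D entries and averages n_p <= k
  tf <- ratio_tables(2, 3, np_policy = "feasible")
  expect_true(all(is.na(tf$regime_ratio$ratio[tf$regime_ratio$n_p > 2])))
  igf <- tf$integration_gain
  expect_equal(igf$mean_ratio[igf$k == 2 & igf$regime == "D" &
                                igf$integration == "TX_CIS_PPI"], 7)
})
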