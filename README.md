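# spsdinfer

Quantifying what single-gene perturbation experiments can — and cannot —
tell you about the Boolean logic of gene regulation.

## The problem

A target gene regulated by *k* regulatory factors (RFs — transcription
factors, miRNAs, …) can be modeled as a Boolean function
`f : {0,1}^k → {0,1}` mapping the ON/OFF states of the regulators to the
state of the target. Knock-down (D, forcing an RF from 1 to 0) and
over-expression (O, forcing 0 to 1) experiments probe this function one
input flip at a time. Two obstacles limit what such experiments reveal:

* **Visibility** — a perturbation whose output does not change gives no
  evidence that the perturbed RF regulates the target at all (think of
  knocking down one input of an OR gate while the other is still ON).
* **Ambiguity** — the observed transitions are typically compatible with
  many Boolean functions, only one of which is the real one.

`spsdinfer` makes both effects exactly computable. It enumerates the
*search space* of all non-degenerate k-input Boolean functions (every
input effective; sizes 10, 218 and 64 594 for k = 2, 3, 4), builds the
**single-perturbation state diagram (SPSD)** of each function — 2^k
state nodes, one edge per available perturbation, solid if the output
changes (visible), dashed otherwise — and averages over the whole space:

* probability of visibility
  `P_v = (1/N_B) Σ_b (1/(k′2^k)) Σ_s N_{k,b,s}`,
  where `N_{k,b,s}` is the visible out-degree of state *s* and
  `k′ = k/2` (D) or `k` (DO);
* per-state and overall full-visibility probabilities
  `P_fv,s = (1/N_B) Σ_b I(N_{k,b,s} = k)`,  `P_fv = mean_s P_fv,s`;
* probability of unambiguity
  `P_ua = (1/(2^k N_B)) Σ_b Σ_s I(s fully visible) / N^cmn_{k,b,s}`,
  where `N^cmn` counts the search-space functions consistent with the
  observed transitions; multi-step experiments chain initial states
  through the SPSD and take the minimum-ambiguity path.

Evidence from other omics layers upgrades visibility: a cis-element at
the target promoter proves a regulator directly (`TX_CIS_PPI` mode makes
everything visible), and a protein–protein interaction with an
already-proven regulator rescues an invisible knock-down edge
(`TX_PPI` mode). The same rules drive the identification of the Boolean
function of a real target gene from perturbation records, cis evidence
and PPI edges — reproduced here for the yeast *GAL4*/*GAL80* → *SWI5*
synthetic-network example shipped in `inst/extdata/`.

## A worked example

The function `F_22^3` (exactly-one-pair-active logic) is probed by a DO
experiment starting from regulator state 3 (tuple 011), then a second
step from state 2:

```r
library(spsdinfer)
f <- decode_index(22, 3)
#> <Boolean function F_22^3: ~RF1*RF2*RF3 + RF1*~RF2*RF3 + RF1*RF2*~RF3>

step1 <- observations_from_step(f, 3, "DO")
step1$observations
#> <observation set, k = 3: 4 of 8 states observed>
#>    1:0 2:0 3:1 7:0
consistent_count(step1$observations)
#> [1] 16

obs <- merge_observations(step1$observations,
  observations_from_step(f, 2, "DO", first_step = FALSE)$observations)
consistent_count(obs, indices = TRUE)$indices
#> [1] 18 22 26 30
```

One step leaves 16 candidate functions; the second step cuts the
ambiguity to 4. Averaged over everything, a single DO step with full
cis+PPI knowledge identifies a 2-input function with 80% probability —
and a second step makes it certain:

```r
unambiguity_probability(2, "DO", "TX_CIS_PPI", 1)
#> <P_ua = 0.8 | k = 2, DO, TX_CIS_PPI, n_p = 1, 10 functions>
unambiguity_probability(2, "DO", "TX_CIS_PPI", 2)$P_ua
#> [1] 1
```

Identifying regulatory logic from real perturbation records:

```r
rec <- read_perturbation_records(
  system.file("extdata", "gal_records.tsv", package = "spsdinfer"))
identify_function(rec, "glucose")$fn
#> <Boolean function F_2^2: RF1*~RF2>   # SWI5 = GAL4 AND NOT GAL80
```

In galactose the identified function reduces to plain activation by
GAL4 (GAL80 ineffective) — see the methods vignette.

## Command line

```sh
inst/cli/spsdinfer build --k 2 --function 4 --regime DO --integration tx --format dot
inst/cli/spsdinfer analyze ambiguity --k 2 --regime DO --integration cis-ppi --steps 1
inst/cli/spsdinfer identify --records gal_records.tsv --condition glucose \
    --cis gal_cis.tsv --ppi gal_ppi_glucose.tsv
```

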