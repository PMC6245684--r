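---
title: "Visibility and ambiguity in Boolean regulatory-logic inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visibility and ambiguity in Boolean regulatory-logic inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spsdinfer)
```

## The model

A target gene with `k` regulatory factors (RFs) is modeled as a Boolean
function: each RF and the target are ON/OFF variables, and the target's
steady state is `f(RF1, ..., RFk)`. This is the usual Boolean-network
abstraction of the sigmoidal dose-response of transcriptional
regulation: a regulator is ON when its product is abundant enough to act.
The package analyzes a single target node exhaustively; multi-node
networks are compositions of such nodes and are out of scope here.

Two conventions fix every number in the package and are worth stating
once:

* a **state number** `s` encodes the regulator tuple with RF1 as the
  most significant bit (at `k = 2`, state 2 is the tuple `10`);
* a **function index** `b` encodes the truth-table output column with
  state 0 as the most significant bit (at `k = 2`, index 8 is the table
  `1,0,0,0`, the NOR gate).

Functions in which some input never changes the output are *degenerate*:
they are really functions of fewer inputs. The **search space** for each
`k` contains only the non-degenerate functions — 10, 218 and 64 594 for
`k` = 2, 3, 4 — and the enumeration is cross-checked against the
inclusion–exclusion closed form
`N_B(k) = sum_j (-1)^j C(k,j) 2^(2^(k-j))`. Constants are representable
(`reduce_to_essential()` returns a flagged 0-input form) but never enter
a search space.

## The single-perturbation state diagram

`build_spsd()` turns a function into the graph of everything one round
of single perturbations can do: 2^k state nodes; a knock-down edge `D_i`
out of every state whose bit `i` is 1, and (under the DO regime) an
over-expression edge `O_i` where it is 0. Knock-downs always decrease
the state number, over-expressions increase it. An edge is **R1-visible**
when the target output differs between its endpoints — that difference
is the only transcriptome-level evidence that the perturbed RF regulates
the target.

### Evidence integration

Three integration modes differ in how non-transcriptomic omics layers
rescue invisible edges:

* **TX** — transcriptome only, R1 is all there is.
* **TX_PPI** — an invisible knock-down edge `D_i` out of state `s` is
  upgraded when another regulator `j` has bit 1 in `s` *and* `j`'s own
  perturbation edge out of `s` is R1-visible. The logic: in the
  unperturbed condition both proteins are present, so a physical
  interaction between RF_i and the *proven* regulator RF_j is
  observable, and the interaction optimistically marks RF_i as an
  indirectly bound regulator.
* **TX_CIS_PPI** — complete cis-element knowledge identifies every
  directly bound regulator and complete PPI knowledge every indirectly
  bound one, before any perturbation. All edges are treated as visible
  and — important and easy to miss — **every state of every function is
  fully visible, in both regimes**, because the full regulator set is
  known a priori rather than inferred from output changes.

Two design choices in the PPI rule deserve justification, because the
written description of such rules is genuinely ambiguous and the package
had to pick one reading:

1. **Only knock-down edges upgrade.** One could argue that after
   over-expressing RF_i the protein is present and an interaction with a
   co-present proven regulator becomes observable, which would upgrade
   `O_i` edges through their destination state. We computed the
   exhaustive `k = 2` unambiguity tables under both readings; only the
   knock-down-only rule reproduces the published reference values for
   every `k = 2` setting (DO/D ratios of 2.0 and 2.5 for one- and
   two-step experiments under +PPI), while the destination-upgrade
   reading overshoots them (2.67, 3.0). Both readings agree on every
   knock-down-side quantity, including the 80%/89%/94% fully-visible
   top-state fractions for `k` = 2, 3, 4 that pin down the anchor
   condition itself. For the DO regime at `k >= 3` the published +PPI
   values fall strictly between the two readings and are reproduced by
   neither — nor by any other variant we constructed (anchor at the
   destination, anchor at both endpoints, upgrade chaining). We keep the
   `k = 2`-validated rule and flag those entries as not reproducible.
2. **No chaining.** An upgraded edge never anchors further upgrades.
   For knock-down-only upgrades chaining is actually a no-op (any
   R1-visible anchor at a state upgrades all its co-present partners in
   one pass), so the choice is conservative documentation rather than a
   numerical decision.

## Visibility probabilities

Over a whole search space the package computes, by exact integer
accumulation with a single final division (sums over at most
64 594 × 64 terms are far below the exact-integer range of doubles,
so this equals rational arithmetic):

* `visibility_probability()` — the average fraction of visible edges,
  `P_v`; identical for D and DO under TX (the diagrams' solid/dashed
  pattern is reciprocal-symmetric), and 1 under TX_CIS_PPI.
* `full_visibility_by_state()` / `full_visibility_probability()` — the
  probability that a state evidences all `k` regulators. Under regime D
  with TX or TX_PPI only the all-ON top state can (there are not even
  `k` edges elsewhere); under DO+TX it is state-independent; under
  DO+PPI it grows with the number of ON regulators.

The top state under D+PPI admits a closed-form cross-check used by the
test suite: all `k` knock-down edges become visible iff at least one is
R1-visible, i.e. iff the outputs are not constant over the states with
at least `k − 1` ON bits.

## Ambiguity and multi-step experiments

One experimental step from initial state `s` measures the output at `s`
and at every perturbation destination. `N^cmn` is the number of
search-space functions consistent with those observations — the
ambiguity of the experiment. `consistent_count()` offers two independent
routes, always in agreement (tested exhaustively at `k = 2`, sampled at
3 and 4): direct filtering of the enumerated space, and completion
counting (2^unobserved completions minus degenerate consistent
completions, by inclusion–exclusion over forced-silent input subsets).

`unambiguity_probability()` averages `1 / N^cmn` over all functions and
all *fully visible* initial states — an experiment that cannot even see
all its regulators is not credited with identifying the function. Full
visibility matters only for the first step: once the regulator set is
established, later steps add observations regardless of output changes.

A multi-step experiment chains initial states through the diagram: each
step performs all available perturbations, and only the choice of the
next initial state branches. The package enumerates all paths of `n_p`
initial states, accumulates each path's observed states, and scores the
minimum `N^cmn` over paths (the optimistic best design). Two properties
follow and are tested: `P_ua` is non-decreasing in `n_p` and in
integration richness, and once a path family covers all 2^k states
(`n_p = 2` at `k = 2`, `n_p = 4` at `k = 3`, under DO) every minimum is
1 and `P_ua` equals `P_fv`.

Computationally, a path's contribution depends only on its observed
*state set*, and all functions sharing a restriction pattern on a state
set are mutually consistent — so one pattern tabulation per state set
scores every function at once. With caching this keeps the heaviest
sweep (`k = 4`, DO, `n_p = 4`: 64 594 functions) in seconds on one CPU.

### Knock-down paths exhaust; step-count conventions

Under regime D every step descends, and from the top state the
experiment dead-ends at state 0 after `k` steps. `unambiguity_probability()`
rejects `n_p > k` under D as undefined. For the summary tables,
however, a "run the protocol for `n_p` steps" reading is operationally
well defined — the experimenter simply stops early — and
`ratio_tables()` therefore defaults to `np_policy = "saturate"`: D
entries with `n_p > k` reuse the `n_p = k` value and are flagged. The
alternative `"feasible"` policy blanks them and averages integration
gains over `n_p <= k` only. The saturate default was chosen because it
reproduces the published `k = 3` summary values (integration gain 18
for D+cis, and the `n_p = 4` DO/D ratios 16 and 8) and the `k = 4` row
(15.3 and 42), where no convention ambiguity exists; the published
`k = 2` row conversely matches the feasible convention (2.5 and 7
rather than 2.25 and 6) — the source tables are internally inconsistent
on this point, and no single convention reproduces both. Dead-ended
paths always keep the observations they accumulated.

`mean_common_count()` reports the average single-step `N^cmn`. Its
averaging set is restricted to fully visible initial states by default
(matching the gate of the unambiguity average; for regime D that means
the top state only); `fully_visible_only = FALSE` gives the unrestricted
mean, since the published description of this average does not
disambiguate the two.

## Identification from records, and the simulator

`identify_function()` turns a table of perturbation records (regulator
states, target state, free-text label and condition) into an observation
set and counts consistent functions over **all** 2^(2^k) truth tables,
degenerate ones included: when the candidate regulator pool comes from
cis/PPI evidence it may be over-complete, and the truthful answer is
then a function that ignores an input — reported through its
essential-input reduction rather than rejected. With the shipped yeast
GAL records: in glucose the identified logic is
`SWI5 = GAL4 AND NOT GAL80`; in galactose it is index 3, whose second
input is ineffective, reducing to plain activation of SWI5 by GAL4 —
the same conclusion under both the dissociation and non-dissociation
models of the Gal4/Gal80 interaction, which differ only in whether the
PPI adds GAL80 to the candidate pool.

`candidate_regulators()` implements the evidence rules: cis-element
hits are direct regulators; the PPI graph is then expanded to a fixpoint
(a protein interacting with any accepted regulator becomes a putative
indirect regulator). The expansion is deliberately optimistic and
clearly tagged — a PPI alone proves nothing, so an empty cis anchor set
yields an empty candidate list. Unlike the SPSD +PPI rule, expansion
here iterates: the narrative of building a regulator list step by step
means "previously proven" grows as the list does.

`simulate_experiment()` is the package's synthetic-data generator. It
emulates exactly the stated protocol: the wild-type state is observed,
each step performs all available perturbations and records every
destination, the next initial state is drawn uniformly from the current
destinations, and (optionally) each non-wild-type record is dropped
independently with a fixed probability. It does **not** emulate
measurement noise on the binary outputs, thresholding of continuous
expression to ON/OFF, unstable intermediate states, or incomplete
penetrance of perturbations — a green round-trip test therefore
establishes the combinatorial soundness of identification (the hidden
function is never excluded, and full coverage pins it uniquely), not
robustness to noisy data. Records are binary by design; calling ON/OFF
from q-PCR or RNA-seq values is the caller's responsibility.

## Numerical choices and degenerate inputs

* All probabilities are ratios of exact integer sums; comparisons
  against published rounded values use round-half-up at the printed
  precision.
* Observation sets reject conflicting duplicate observations loudly
  (they indicate a malformed experiment table), and deduplicate
  identical ones silently.
* Ties among minimum-ambiguity paths are irrelevant to the score; when
  path enumeration produces duplicate state sets they are merged, and
  deterministic iteration order makes every output byte-stable.
* `k = 1` is supported (search-space size 2) for completeness;
  `k > 4` is allowed but warns: enumeration grows as 2^(2^k).
* State-0 initial states under regime D have no perturbations; the
  experiment still observes the wild-type output, which is why such
  states contribute `N^cmn` over a one-state observation set rather
  than the whole space.

## Known limitations

* Steady-state semantics only: time-series equivalence for cyclic
  attractors is not implemented.
* The +PPI analysis is optimistic by construction (complete, error-free
  interaction knowledge), and the DO-regime +PPI reference values for
  `k >= 3` could not be reproduced under any rule reading we tried (see
  above); treat those published entries with caution.
* No restricted "biologically meaningful" function subsets are shipped;
  `enumerate_search_space(filter = ...)` accepts one if you have one.
* The experiment-design optimizer (choosing the next step adaptively)
  is out of scope.
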