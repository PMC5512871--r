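---
title: "Dating retroviral lineages with retroclock: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating retroviral lineages with retroclock: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroclock)
```

## The problem

Extrapolating viral divergence dates across timescales is treacherous because
measured viral substitution rates are time-dependent: rate estimates made
over short observation windows are orders of magnitude higher than rates
implied by deep calibrations. Naive application of a short-term rate to a
deep node therefore underestimates its age catastrophically. `retroclock`
implements the correction that makes deep dating defensible for lineages
with a reliable co-speciation calibration — foamy viruses (FVs) and their
endogenous relatives (FLERVs) being the canonical case — together with the
two auxiliary clocks used around it: LTR-divergence dating of endogenous
elements, and event-based co-speciation testing that justifies borrowing
host dates in the first place.

## The power-law TDRP model

Let `S` be the total per-lineage substitutions (substitutions/site)
accumulated from a chosen focal tip back to an internal node of a non-clock
phylogeny, and `T` the age of that node in Myr. Under a power-law decay of
apparent rate with timescale, `S` and `T` obey

$$\log_{10} T = \alpha + \beta \, \log_{10} S.$$

`fit_power_law()` estimates `alpha` and `beta` by ordinary least squares on
the log10-transformed pairs, reporting the adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-2)$ for the single-predictor model; at least
three calibration points are required (below that the adjusted $R^2$ is
undefined) and all `S`, `T` must be positive. The regression direction is
deliberately `T` on `S`: ages of uncalibrated nodes are predicted from their
substitution estimates via `extrapolate_age()`, which evaluates
$T = 10^{\alpha + \beta \log_{10} S}$. Extrapolation beyond the calibration
range is permitted — deep nodes are precisely the use case — and flagged in
the output of `posterior_dating()`.

Two invariances are useful for validation and are covered by tests: the fit
is scale-equivariant in `S` (rescaling all `S` by `c` leaves `beta` and the
adjusted $R^2$ unchanged and shifts `alpha` by $-\beta \log_{10} c$), and a
calibrated node fed back through the model returns exactly its fitted OLS
residual.

### Measuring S on a focal lineage

`lineage_depths()` walks from a focal tip (for the FV calibration, the
chimpanzee simian foamy virus tip) to the root, accumulating branch lengths.
Measuring node heights this way, on a tree with no clock imposed, confines
the mixed host/virus rates of endogenous taxa to their own terminal branches:
the internal branches along the focal lineage reflect exogenous viral
evolution only. Calibration and target nodes are specified reproducibly as
the most recent common ancestors of named tip sets (`mrca_node()`), and the
package enforces that every such node actually lies on the focal lineage.

### Propagating uncertainty

`posterior_dating()` repeats the resolve–fit–extrapolate cycle over every
tree of a posterior sample, yielding a sample of extrapolated ages per target
node, summarised by the median and the 95% highest posterior density
interval. `hpd_interval()` returns the shortest contiguous window of the
sorted sample containing at least `ceiling(mass * n)` points, breaking ties
toward the smallest low endpoint — a deterministic convention checked
against an exhaustive window scan in the tests.

Calibration ages enter either as fixed medians (`t_sampling = "median"`, the
default and the reproducible proxy) or drawn per replicate from a lognormal
whose 2.5% and 97.5% quantiles match the calibration interval
(`t_sampling = "interval"`). The lognormal is a modelling choice: host date
posteriors are positive and right-skewed, and matching the published
interval endpoints uses exactly the information a calibration table carries.
Both modes are seeded.

### What the synthetic posterior emulates

`simulate_tdrp_posterior()` builds a ladder tree whose focal-lineage depths
equal a requested `S` vector and multiplies each branch by independent
lognormal noise with mean 1 and coefficient of variation `rel_noise_sd`
(parameterised as `sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2/2`).
This reproduces the feature that matters for the dating machinery — jittered
per-lineage depths across posterior samples around a known power law — but
not topological uncertainty, among-lineage rate correlation, or alignment
error in real Bayesian samples. Recovery tests on these fixtures
(held-out-node coverage, parameter recovery at the calibrated operating
point with `rel_noise_sd = 0.1` and a few hundred trees) therefore validate
the estimator, not the upstream tree inference. The default simulation sizes
used in the test suite (300 trees, 50 replicates) were chosen as the
smallest at which the coverage statistics are stable.

## LTR-divergence dating

The two LTRs of a provirus are identical at integration and diverge
independently afterwards, each at (approximately) the neutral rate `r` of
the host genome, so an element's age is $(d/2)/r$ with `d` the pairwise
distance between its LTRs. `tn93_distance()` implements the Tamura–Nei
(1993) estimator, which separates the two transition classes (A↔G, C↔T) and
allows unequal base frequencies:

- frequencies are the empirical frequencies averaged over both sequences
  (the MEGA convention for pairwise distances);
- columns with a gap or ambiguity in either sequence are excluded
  (pairwise complete deletion);
- saturation (a non-positive logarithm argument) is an explicit error, not a
  silent `NaN`;
- compositions lacking an entire base class drop the vanished terms: with
  averaged frequencies, an observed transition forces both of its base
  frequencies to be positive, so nothing observable is ever discarded.

The estimator is validated three ways: closed-form hand evaluation on a
constructed pair, agreement with `ape::dist.dna(model = "TN93")`, and
consistency on pairs simulated under the exact TN93 transition
probabilities (`simulate_tn93_pair()` uses the matrix exponential of the
scaled rate matrix, so the simulated expectation equals the nominal
distance). `ltr_age()` accepts a vector of rates and reports the age at
each bound — published neutral-rate estimates are often ranges (for
amphibians, 0.924–1.53 × 10⁻⁹ substitutions/site/year), and the age at
each bound is more honest than a single point.

## Co-speciation maximisation and the permutation test

`max_cospeciations()` computes the exact maximum number of co-speciation
events over untimed event-based reconciliations of a virus tree into a host
tree. This is the objective induced by vertex costs of −1 for co-speciation
and 0 for duplication, duplication-plus-host-switch, loss, and failure to
diverge. The dynamic programme scores each parasite internal node placed on
each host node as either

- a **co-speciation**: at least two children matched into distinct child
  subtrees of the host node (resolved at polytomies by an exact
  maximum-weight assignment of parasite-child subtrees to host-child
  subtrees), any further children switching freely; or
- a **duplication / duplication + switch**: at least one child remains
  within the host node's subtree, the rest may switch anywhere.

The at-least-one-child-stays rule mirrors the structure of event-based
reconciliation, where a switch carries one daughter lineage away; without
it, an internal node could be parked in an arbitrary empty host subtree
with *all* of its children switched out, inflating the count (a tanglegram
whose parasite tips all share one host tip would score 1 instead of 0).
Losses are free, switch targets are otherwise unconstrained, and no host
timing is enforced — so the result is the untimed maximum, an upper bound
on what a timed genetic-algorithm search can find; both trees may contain
polytomies, e.g. after `collapse_low_support()` (the conventional 0.80
posterior-probability cut-off). The DP is verified against exhaustive
enumeration of all node placements on hundreds of small tanglegrams.

`random_tip_mapping_test()` permutes the multiset of host assignments among
the virus tips (preserving how often each host tip is used), recomputes the
maximum for each of `N` permutations, and reports `p = k/N`, displayed as
`< 1/N` when no permutation reaches the observed count. Calibration is
checked by the super-uniformity of p-values under randomized associations.

`simulate_cophylogeny()` generates ground-truthed tanglegrams by threading
parasite lineages through a Yule host tree (co-speciate with probability
`1 - switch_prob` at each host split, else jump to a random contemporary
lineage; lineages lost with probability `loss_prob`). The recorded truth
counts only *recoverable* co-speciations — splits whose surviving
descendants stayed inside their natal host subtrees — because an event whose
descendants all switched away leaves no witness in tip data; defined this
way, the truth provably lower-bounds the reconciliation maximum, which the
tests confirm replicate-by-replicate.

## Paired-LTR and TSD detection

`find_ltr_pairs()` finds same-strand repeat pairs by exact 12-mer seeding,
diagonal clustering of seed matches, and local pairwise alignment of the two
candidate windows (BLAST-like scoring: match 2, mismatch −3, gap open 5,
gap extend 2). Defaults (`min_len = 200`, `min_identity = 80`,
`max_gap = 25000`) target young, high-identity LTR pairs; old, heavily
diverged pairs are out of scope. Because a local alignment can creep a few
nucleotides past the true repeat ends through chance homology (including
TSD-like motifs inside the element), boundaries are refined by trimming the
alignment to its maximal-scoring core under a stricter column scoring and
re-extending outward through matching columns, jumping an isolated mismatch
only when backed by four further exact matches. All coordinates in reports
are 0-based half-open; GFF3 output converts to 1-based inclusive.

`find_tsd()` then searches for the longest exact 4–6 nt match between the
windows immediately flanking the element, allowing ±2 nt of boundary slack
because LTR edge inference is approximate. A mutation striking the outermost
bases of an LTR truncates the homology evidence itself, so boundary recovery
within ±2 nt cannot be guaranteed at arbitrary divergence; at the
young-element operating point (paired-LTR distances up to ~1%), recovery
rates in the tests exceed 95%, and at the generator default (identical
copies) boundaries are exact. The TSD length range is a configurable
default, not a fixed constant of the biology.

## Numerical and design notes

- Newick I/O is delegated to `ape` with added validation; branch lengths are
  written with 10 significant digits so trees round-trip exactly. Internal
  node labels in `[0,1]` are posterior supports; labels in `(1,100]` are
  bootstrap percentages and are rescaled; labels above 100 are rejected.
  Nodes without support (including the root) are never collapsed.
- `collapse_low_support()` deletes the weak edge entirely; children keep
  their own branch lengths. The collapsed tree is used for topology-based
  co-speciation counting, where lengths are irrelevant.
- HPD ties, permutation seeds, and all generators are deterministic given
  their seed; identical configurations produce byte-identical outputs.
- `run_pipeline()` writes a manifest (tool version, config hash, input
  digests, seeds, per-stage parameters) next to every output set.

## Limitations

The TDRP model assumes the focal lineage's rate-decay dynamics transfer to
the extrapolated nodes; that is a biological assumption, not something the
package can check. LTR dating assumes neutral, independent evolution of the
two LTRs — gene conversion between them deflates `d` and the inferred age,
and is not detected here. The co-speciation maximum is untimed; costed
event regimes other than co-speciation maximisation, and timed
reconciliations, are out of scope.
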