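---
title: "Conversion-aware analysis of duplicated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conversion-aware analysis of duplicated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Tandemly duplicated gene families such as the vertebrate Toll-like
receptor 1 (TLR1) family — TLR1, TLR2, TLR6, TLR10 in mammals; TLR1A/B
and TLR2A/B in birds — often show gene trees in which paralogues from
the same species cluster together instead of with their orthologues.
Two very different processes can produce that pattern: **gene
conversion** (non-reciprocal transfer of sequence between tandem
copies, homogenizing them region by region — concerted evolution) and
**convergent evolution** of the protein sequence. Telling them apart,
restricting phylogenetic inference to conversion-free regions, dating
the duplication and conversion events, and asking which codons and
residue pairs are under positive selection or co-evolving, together
form one coherent analysis. `concertr` implements that analysis as a
set of composable stages plus a simulator that generates data with
known truth for every stage.

# Stages and their models

## Conversion detection

For each sequence pair of a group alignment, the scan lists the
**polymorphic sites** (columns with at least two non-gap states across
the group; columns containing gaps or `N` are excluded so alignment
artifacts cannot seed fragments) and marks where the pair matches.
With the default scoring, a fragment is a maximal run of consecutive
matching polymorphic sites. Its significance is the tail probability
of a run at least that long when the pair's matches and mismatches are
arranged uniformly at random — computed *exactly* by inclusion–
exclusion over compositions where that is numerically stable, and by a
Poisson clump approximation in the moderate-tail regime where the
alternating series cancels catastrophically. The reported `bcka_p`
multiplies this tail by the number of ordered-pair comparisons in the
scan (Bonferroni) and caps at 1; `sim_p` is the matching permutation
p-value, `(1 + #{permutation max >= observed}) / (R + 1)`, with 10,000
permutations by default.

Real conversion tracts older than a few My accumulate internal
mismatches. The optional penalized scoring (`mismatch_penalty =
"auto"`, i.e. `max(1, 2p/(1-p))` at background match proportion `p`)
finds maximal-scoring segments (iterated Kadane) instead of pure runs,
with a Karlin–Altschul-style tail, `P ~ (D+1) exp(-lambda * score)`,
where `lambda` solves the usual moment equation. The default stays the
strict no-mismatch rule; the penalized mode is the right tool for
older tracts.

**Bootscan** complements the pairwise scan: per sliding window
(defaults 200 columns, step 20, 1,000 replicates), columns are
resampled, F84 maximum-likelihood-corrected distances feed a
neighbor-joining tree, and the support for the query being sister to
each reference is recorded. A conversion tract shows as a window run
in which the query's best-supported partner switches to its paralogue.

## Regions and trees

The top fragment tiles the alignment into converted and
conversion-free regions (the familiar N / Central / C naming, 1-based
inclusive columns in every report; all internal slicing is 0-based
half-open with a single conversion point). Codon-frame-breaking region
boundaries are trimmed inward to the enclosing codon with a warning.
Conversion-free regions feed distance (F84 closed form, HKY or JTT
pairwise ML) and likelihood (HKY85 or JTT + invariant sites + 4
discrete gamma classes, via phangorn's pruning engine) tree building,
non-parametric bootstrap (column resampling; bipartition counts on the
point tree), and quartet likelihood mapping (posterior weights of the
three quartet topologies assigned to the seven simplex regions by the
nearest of the seven typical points; the corner fraction is the
"resolved" share).

## Codon site models

The positive-selection machinery is built around the Goldman–Yang
codon model: 61 sense codons, transition/transversion ratio kappa,
nonsynonymous/synonymous ratio omega, target-codon frequencies (F3x4
default; F61 and equal available), zero rate for multi-nucleotide
changes, mixture-level rate normalization so one branch-length unit is
one expected codon substitution. Site-class mixtures M0, M1a, M2a, M7
(beta, 10 equal-probability classes by mean), M8 (beta plus a free
omega > 1 class) and M8a (the same with omega fixed at 1) are fitted
by BFGS on transformed parameters (log for rates, logistic/
stick-breaking for proportions, `log(omega - 1)` for the
positive-selection class) from two starting points; `selection_scan()`
warm-starts each alternative from its null, which also guarantees the
nesting inequalities numerically. Branch lengths enter through the
supplied tree; per model a single tree-scale factor is re-optimized
(the option `branches = "all"` frees every branch length — with the
tree coming from the tree stage, the scale factor absorbs unit and
model differences at a fraction of the cost, and LRT calibration is
unaffected at these problem sizes, which is why the scale variant is
the default). Nested pairs are compared by `2 * delta lnL` against
chi-squared (df 2, 2, 1 for M1a/M2a, M7/M8, M8a/M8), with the
boundary-corrected `0.5 chi2_0 + 0.5 chi2_1` p-value additionally
reported for M8a/M8. Sites are identified by naive empirical Bayes at
the MLEs (posterior of the omega > 1 classes, threshold 0.9), labeled
by ungapped position and residue of a designated reference sequence
("286Q" style). BEB-style integration over parameter uncertainty is
deliberately out of scope; NEB site lists can differ slightly from
tools that use BEB.

The likelihood core (rate-matrix construction, symmetrized
eigendecomposition, mixture rate normalization, Felsenstein pruning
with underflow rescaling) is compiled code, verified in the test suite
against brute-force enumeration over ancestral codon states on 3- and
4-taxon toys to 1e-8.

## Clock dating

Dating follows a two-phase protocol: first the substitution nuisance
parameters are estimated without a clock (kappa and omega via an M0
fit for codon data; kappa and the gamma shape via phangorn for
nucleotide data); then, with those fixed, relative node heights of the
rooted tree are fitted by clock-constrained maximum likelihood (root
height log-transformed, every other internal height a logistic
fraction of its parent, so child < parent by construction). The local
model adds one rate multiplier on user-flagged branches. Calibrations
(point or interval, on MRCAs of named leaf sets) then scale heights to
ages: the overall rate is the geometric midpoint of the feasible
interval intersection, or a least-squares fit against interval
midpoints when the intersection is empty. Conversion events are dated
from the homogenized tract itself: since a converted tract has a
star-like two-lineage history, its age is the tract's pairwise
divergence (under the clock fit's own substitution model) divided by
twice the rate, with an interval from the rate interval. A
zero-divergence tract is flagged "recent or ongoing".

## Co-evolution

The correlated-substitution scan follows the CAPS logic: for each
informative site, the vector over unordered sequence pairs of BLOSUM80
transition scores divided by the pair's divergence-time proxy
(Poisson-corrected protein distance, floored at 0.01 so identical
pairs stay usable), centered; co-evolution is the Pearson correlation
of two sites' vectors. Significance comes from a large resampling
(default 10,000) of random site pairs — the empirical null carries the
shared-genealogy correlation that any two independent sites on the
same tree exhibit — with strict exceedance counting (null draws tied
with a candidate at numerical resolution are patterns identical to it,
typically the truly co-evolving pairs re-sampled into the null, and do
not count as more extreme) and a step-down monotone pass over the
ranked candidates. Sites whose variation rests on a single sequence
are excluded by default (`min_minor = 2`): such columns carry at most
one substitution, and their two-valued vectors collide exactly with
every other such column, flooding the null with perfect correlations.
The null-calibration suite verifies that on coupling-free data the
significant fraction stays at the nominal level. Significant pairs are
grouped into connected components and can be filtered by cellular
compartment (extracellular / transmembrane / cytoplasmic intervals on
the reference protein) and exported as GraphML/SIF networks with the
correlation as edge attribute.

# The simulator

`simulate_gene_family()` evolves codon sequences along a duplicated
gene tree (an ultrametric species tree in My plus a duplication
predating its root, giving `<species>_A` and `<species>_B` tips) by
exact per-site Gillespie simulation under GY94 with discrete per-site
omega classes — event-level simulation rather than endpoint matrix
sampling, so conversion events can interrupt branches at exact times.
A conversion event on a species' terminal branches copies the donor
paralogue's tract state at the event time onto the acceptor, after
which both evolve independently to the present; events are restricted
to terminal branches, matching the species-specific recent conversions
the study design emulates. Coupled site pairs substitute
branch-synchronously: whenever either partner's residue changes on a
branch, with the configured coupling probability both land on the
*same* residue drawn from the allowed set, and coupled sites carry a
substitution-rate boost (default 3x) mimicking the elevated exchange
rate of interacting interface residues; with coupling 0 the generator
reduces exactly, seed for seed, to the independent-sites simulator.
Everything is deterministic given the config seed, and the full config
round-trips through a plain-text file.

`tlr1_family_preset()` fixes the study conditions: four bird and four
mammal species with a bird–mammal split at 317.5 Mya, duplication at
359 Mya, 800 codons, mutation rate 1.25e-3 codon substitutions per
codon site per My (chosen so paralogue divergence matches the family's
observed identity levels), kappa 2.5, omega classes (0.05, 0.4, 2.5)
with proportions (0.55, 0.40, 0.05), and species-specific conversion
tracts covering the C-terminal third at 2–20 Mya (birds) and 5–45 Mya
(mammals). What the generator does *not* emulate: insertions/deletions
(all alignments are gap-free unless the user introduces gaps),
alignment error, codon-usage bias beyond the frequency model,
rate variation along the genome beyond the omega classes, and
recombination other than interval conversion — so passing recovery
tests demonstrate correctness of the estimators under the model, not
robustness to real-data misalignment or composition artifacts.

# Numerical choices and degenerate inputs

* Identity denominators exclude columns with a gap in either sequence;
  `N`/`X` count as mismatches (this can shift reproduced identity
  means by under a percent relative to other conventions).
* Terminal stop codons are stripped with a message; internal stops are
  errors everywhere.
* Saturated distances (F84 log-domain violations) are flagged
  infinite; NJ excludes the affected taxa with a warning rather than
  clamping.
* Optimizers: BFGS with `reltol 1e-9` on transformed parameters;
  LRT statistics are clamped at zero against optimizer noise; all
  stochastic stages take explicit seeds and are reproducible
  bit-for-bit.
* The exact run-length tail switches to a Poisson clump approximation
  only where the alternating series loses precision; the switch is
  validated against Monte Carlo in the tests.

# Problem sizes used by the validation suites

The calibration and recovery suites run at sizes chosen to exercise
each estimator's operating regime: type-I error of M1a/M2a on 50
conversion-free simulations of 6 sequences x 300 codons; M7/M8 power
and site recovery on 20 simulations of 12 sequences x 300 codons with
5% of sites at omega 4; tract localization on 100 simulations of a
450-column tract among 8 sequences x 1800 columns, with 100
conversion-free scans for the false-positive rate; clock recovery on
10 simulations of 8 sequences x 667 codons; co-evolution recovery and
null calibration on 20 + 20 simulations of 12 sequences x 300 sites
with three fully coupled pairs. The acceptance script
(`scripts/acceptance.R`) re-runs the study-shaped preset end to end
and reports the recovered duplication age, conversion-age range,
tract overlap, codon-usage bands, selection statistics and
co-evolution sensitivity.

# Known limitations

* Tree search is NJ plus optional NNI hill climbing, not a full ML
  search; printed bootstrap proportions for marginal splits need not
  reproduce values obtained with more exhaustive searches.
* The mammalian/avian group sizes in the published table differ in
  two places from the running text (TLR6 15 vs 12, TLR10 12 vs 15);
  reproductions follow the table's counts.
* Conversion dating assumes the tract's two-lineage star history;
  overlapping or chained conversion events between more than two
  copies would bias those ages.
* NEB site identification understates uncertainty relative to BEB,
  particularly for small groups (4 sequences).
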