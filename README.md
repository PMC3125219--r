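# concertr

Conversion-aware evolutionary analysis of duplicated gene families.

Tandemly duplicated genes — the vertebrate Toll-like receptor 1 family
(TLR1, TLR2, TLR6, TLR10 in mammals; TLR1A/B and TLR2A/B in birds) is
the motivating case — frequently undergo **gene conversion**:
non-reciprocal transfer of sequence between copies that homogenizes
them region by region. The result is gene trees in which paralogues
from one species cluster together, masking the true duplication
history. `concertr` implements the full analysis that untangles this:

* **Conversion detection** — Sawyer-style pairwise fragment scans over
  polymorphic sites, scored by the exact tail probability of the
  longest match run (or a Karlin–Altschul tail for penalized
  mismatch-tolerant segments), with permutation (`sim_p`) and
  Bonferroni-corrected analytic (`bcka_p`) p-values; sliding-window
  **bootscan** profiles (NJ on F84 ML-corrected distances) to localize
  breakpoints.
* **Region partitioning** of codon alignments into converted and
  conversion-free regions (1-based inclusive coordinates, codon frame
  preserved).
* **Phylogenetics** — F84/HKY/JTT distances, neighbor joining, ML
  branch lengths with invariant sites + discrete gamma (two-round
  protocol), nonparametric bootstrap, quartet likelihood mapping.
* **Clock dating** — global and local molecular clocks on codon or
  nucleotide data with fossil calibrations (two-phase: substitution
  parameters first, then clock-constrained node heights); conversion
  events dated from the homogenized tract's divergence,
  `age = d / (2 * rate)`.
* **Positive selection** — a Goldman–Yang codon model (61 sense
  codons, kappa, omega, F3x4/F61/equal frequencies) with site-class
  mixtures M0, M1a, M2a, M7, M8, M8a; likelihood-ratio tests of the
  nested pairs (M1a/M2a, M7/M8, M8a/M8 with a boundary-corrected
  option) and naive-empirical-Bayes identification of sites with
  omega > 1, labeled "286Q"-style on a reference sequence.
* **Co-evolution** — CAPS-style correlated-substitution scanning
  within and between proteins (BLOSUM80 scores over sequence pairs,
  time-corrected, Pearson correlation, resampled null with step-down
  correction), compartment filtering, GraphML/SIF network export.
* **Codon-usage concordance** — the conversion-vs-convergence
  diagnostic: among residues identical in a pair, the fraction encoded
  by the identical codon, compared between regions.
* A **simulator** (`simulate_gene_family()`) that evolves codon
  sequences by exact Gillespie simulation along a duplicated gene
  tree, with interval conversion events at chosen times, discrete
  omega site classes and branch-synchronously coupled residue pairs —
  so every stage above is testable by recovery against known truth.

## Worked example

Simulate a study-shaped family (duplication 359 Mya, four bird-like
and four mammal-like species, species-specific conversion tracts in
the C-terminal third), scan the bird-like group and partition it:

```r
library(concertr)

sim   <- simulate_gene_family(tlr1_family_preset(seed = 1))
birds <- paste0(rep(c("birdW","birdX","birdY","birdZ"), each = 2),
                "_", c("A","B"))
grp   <- sim$alignment[birds, ]
pairs <- cbind(paste0(c("birdW","birdX","birdY","birdZ"), "_A"),
               paste0(c("birdW","birdX","birdY","birdZ"), "_B"))

fr <- scan_gene_conversion(grp, pairs = pairs, mismatch_penalty = "auto")
head(as.data.frame(fr)[, c("idA","idB","begin","end","n_poly","n_dif",
                           "tot_difs","bcka_p")], 4)
#>       idA     idB begin  end n_poly n_dif tot_difs   bcka_p
#> 1 birdX_A birdX_B  1624 2400    193     2      360 3.96e-39
#> 2 birdW_A birdW_B  1624 2400    193     1      334 5.32e-36
#> 3 birdY_A birdY_B  1590 2400    196     9      352 3.08e-34
#> 4 birdZ_A birdZ_B  1590 2400    196    14      349 1.15e-30
```

Every within-species paralogue pair shows one dominant C-terminal
fragment (columns ~1624–2400; the simulated tract is 1600–2400) at
vanishing corrected p-values — the signature of concerted evolution.
Tiling the alignment and applying the codon-usage diagnostic:

```r
regions <- conversion_regions(fr$begin[1], fr$end[1], ncol(grp))
cc <- codon_usage_concordance_group(grp, pairs, regions)
cc$aggregate
#>   region n_conserved n_identical_codon fraction
#> 1      C        1026              1012    0.986
#> 2      N        1657              1135    0.685
```

Conserved residues in the converted C-terminal region use the
identical codon 98.6% of the time versus 68.5% elsewhere: sequence
identity there came from conversion, not convergent protein evolution
(`conversion_vs_convergence_verdict()` formalizes the call). Clock
dating on the conversion-free region (species split calibrated at
310–325 Mya) recovers the duplication at ~363 Mya against a simulated
truth of 359, and `date_conversion_event()` on the tract recovers the
per-species conversion times (simulated 2–45 Mya, estimated 1.5–41).

`run_pipeline(pipeline_config(...))` chains all stages (scan →
partition → trees → dating → selection → co-evolution → diagnostics)
with deterministic seeds and TSV/newick/GraphML outputs;
`inst/scripts/pipeline.R` is a thin command-line front-end.

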