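---
title: "Scanning genomes for transcription-factor targets and relating them to hibernation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for transcription-factor targets and relating them to hibernation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hibtarget)
```

## The scientific question

Hibernating mammals switch their winter metabolism from glucose to
stored fat, and the nuclear receptor PPARα is a master regulator of the
lipid-catabolic program.  Two genome-scale signatures would support an
adaptive role for such a regulator: (i) its coding sequence should be
under strong purifying selection in hibernating lineages, and (ii) the
genomes of hibernators should be more "receptive" to it — more genes
carrying predicted binding sites, and stronger predicted binding — than
the genomes of non-hibernators.  `hibtarget` implements the complete
computational pipeline for both signatures, together with seeded
synthetic-data generators that stand in for the dozens of mammalian
genome assemblies the full analysis requires.

The package has four analysis layers and one simulation layer:

1. **Motif scanning** (`pfm_to_pwm`, `score_distribution`, `scan_pwm`)
   with exact p-values;
2. **Target-gene calling** (`derive_regions`, `call_targets`,
   `summarize_species`, `annotate_peaks`, `make_window`);
3. **Codon branch models** (`fit_branch_model`, `lrt`,
   `conservation_summary`);
4. **Trait correlation** (`students_t_test`, `phyl_anova`,
   `threshold_model_mcmc`, `ddct_fold_change`);
5. **Synthetic data** (`generate_genome`, `generate_cohort`,
   `simulate_codon_alignment`, `simulate_threshold_traits`,
   `generate_chip_peaks`).

## Motif model and exact p-values

A motif is a position frequency matrix (PFM): counts of A/C/G/T per
column.  With a background model $p_b$ (order-0, estimated from the
scanned sequences and smoothed with the uniform distribution at total
mass $4\,\mathrm{bg\_pseudo}$), the log-odds weight of base $b$ at
column $j$ is

$$ w(b,j) \;=\; \mathrm{round}\!\left( \log_2 \frac{(n_{bj} +
\mathrm{pseudo}\cdot p_b) / (N_j + \mathrm{pseudo})}{p_b},\;
\mathrm{decimals}\right). $$

The defaults (`pseudo = 1`, `decimals = 1`, `bg_pseudo = 0.01`, both
strands, upper p-value threshold $5\times10^{-7}$) are the scan
operating point used throughout the package.  Design choices a reader
should know about:

* **Log base.**  Weights are base-2 log-odds (bits).  Affinity scores
  are therefore comparable across species scanned with the same PFM.
* **Rounding before everything.**  Weights are rounded to the
  `decimals` lattice *before* both scanning and the p-value
  computation, so a hit's p-value is exactly the tail mass of its
  score under the same lattice.  `score_distribution` convolves the
  per-column weight distributions by dynamic programming on the integer
  lattice; for any width ≤ 6 it agrees exactly with exhaustive
  enumeration of all $4^w$ words (a property the test suite asserts for
  twenty random matrices).
* **Discreteness at the threshold.**  Because scores are discrete, the
  per-window hit probability of a scan "at $p \le u$" is the largest
  attainable tail value $\le u$, not $u$ itself (`effective_pvalue`
  exposes it).  The false-positive calibration fixture in the test
  suite is a 20-column moderate-information matrix chosen so that this
  attainable value sits within 0.01% of the $5\times10^{-7}$ operating
  threshold, which makes the Poisson expectation
  $2\,(L-w+1)\,u$ a faithful reference.
* **Ambiguity and strands.**  Windows containing `N` are skipped;
  both-strand scanning reports per window-strand p-values without a
  cross-strand correction; overlapping hits are all reported.
* **Coordinates.**  0-based half-open internally; 1-based on
  GFF3-facing output.

## Target genes, affinity scores and regulatory windows

A gene is a **target** when at least one motif hit overlaps (≥ 1 bp)
its introns, exons, or the 10 kb window upstream of its TSS.  The
per-gene **affinity score** is the best (maximum) hit score among those
regions — "only the highest score per gene is adopted" — and the
per-species **target ratio** is the number of target genes over the
number of annotated genes.  Mean affinity averages over target genes
only.  When annotations carry isoforms, the longest transcript is
canonical.

ChIP peaks are classified by their midpoint into
5'UTR > Coding Exon > 3'UTR > Intron > UpStream > DownStream >
Distal_Region (beyond 20 kb from any gene), a fixed precedence order we
chose because wide peaks can span several features; the ratios sum
to one by construction.  TSS-anchored windows come in three kinds —
`TSS_Up` ends at the TSS, `TSS_Body` starts at it, `TSS_Around` is
symmetric about it (our reading of "around") — at 2.5/5/7.5/10 kb, all
strand-oriented and clipped at chromosome ends.

## Codon branch models

Coding-sequence selection is quantified with a GY94-style codon model:
61 sense-codon states, rate proportional to the target codon frequency
$\pi_j$, multiplied by $\kappa$ for transitions and by $\omega = d_N/d_S$
for amino-acid-changing substitutions, scaled to one expected
substitution per codon per unit branch length.  Codon frequencies
default to F3x4 (position-specific base frequencies estimated from the
alignment); F1x4 and uniform are available.  Four branch models are
fit by maximum likelihood:

| model | free $\omega$ | use |
|---|---|---|
| `one_ratio` | 1 shared | null for heterogeneity tests |
| `fixed_omega1` | none ($\omega = 1$) | neutrality null |
| `free_ratio` | one per branch | heterogeneity alternative |
| `two_ratio` | background + labeled classes | foreground-lineage tests |

Likelihoods are computed by Felsenstein pruning over the 61 states
(an Rcpp core with per-pattern rescaling); gapped or ambiguous codons
are missing data (all-ones partial likelihoods).  The optimizer is
monotone coordinate ascent: golden-section search for $\kappa$ and each
free $\omega$ (on a log scale, with an adaptively expanding window),
and per-branch line searches on conditional-likelihood partials with a
backtracking safeguard, iterated until the log-likelihood changes by
less than `tol` (default $10^{-5}$).  Because each stage never
decreases the likelihood, warm-starting an alternative model from its
null's optimum guarantees a non-negative likelihood-ratio statistic.
`lrt` compares $2\Delta\ell$ with the $\chi^2$ upper tail at
$\Delta\mathrm{np}$ degrees of freedom, where the parameter count is
branches + $\kappa$ + free $\omega$'s (frequencies are counted as
estimated, not free, matching the usual branch-model accounting).
Per-branch expected substitution counts split the fitted branch length
into nonsynonymous and synonymous parts via the equilibrium flow
decomposition of the generator, reported as `NdN` and `SdS` over the
alignment.

Branch classes are read from CODEML-style `#1` suffixes on newick
labels (`labeled_tree`), or supplied explicitly per edge.

Amino-acid conservation (`conservation_summary`) calls a column
identical when all non-gap residues agree; with a two-group partition
it lists sites conserved in one group but variable in — or fixed
differently from — the other, the comparison used to contrast
hibernating and non-hibernating lineages.

## Correlating hibernation with genome-derived scores

Three methods connect a binary hibernation flag with a per-species
continuous statistic (target ratio or mean affinity):

* **Student's t-test** — classic pooled-variance two-sample test
  (`var_equal = FALSE` gives Welch), because the original comparison is
  explicitly a Student test.
* **Phylogenetic ANOVA** — the observed one-way F statistic is referred
  to a null distribution obtained by simulating Brownian motion on the
  phylogeny, with the rate estimated from the data by GLS (identical to
  the mean squared independent contrast on dichotomous trees, but also
  defined on stars and polytomies).  The p-value uses the add-one
  correction $(1 + \#\{F_{sim} \ge F_{obs}\})/(n_{sim}+1)$, so it is
  never exactly zero.  On a star phylogeny it converges to the
  parametric ANOVA p, a limit the tests check.
* **Threshold model** — an unobserved liability and the observed value
  evolve as correlated Brownian motion; the binary state is the sign of
  the liability.  The MCMC Gibbs-samples tip liabilities from
  sign-constrained conditional normals (Robert's exponential rejection
  sampler in the far tails) and updates the correlation $r$, the value
  scale $\sigma$, and the two root means by adaptive random-walk
  Metropolis.  Identifiability fixes the liability scale at 1; $r$ has
  a uniform prior on $[-1, 1]$, and the scale and means carry flat
  priors within wide bounds.  Default burn-in is 20% with no thinning.
  Since the tail quantity for the reported significance is not uniquely
  defined for a posterior sample, the result exposes
  `p_r_le_0 = P(r \le 0 \mid \mathrm{data})` and labels it as such, next
  to the central 95% credible interval.

## What the generators emulate — and what they do not

`generate_genome` draws an i.i.d. background chromosome (default
30%/20%/20%/30% A/C/G/T), lays out identically structured genes
(3 exons × 200 bp, 400 bp introns, terminal 100 bp UTRs, 12 kb
intergenic gaps so the 10 kb upstream window of one gene never touches
its neighbor), and plants motif instances into upstream/exon/intron
regions at Poisson rates.  Planting **strength** interpolates between
sampling bases from the PFM columns (0) and writing the consensus (1).
Every generator is a pure function of recipe + seed: reruns are
byte-identical, and each emits a truth table (planted coordinates,
intended target labels, intended peak classes, true $\omega$ per
branch, true $r$).

`generate_cohort` emulates the comparative design — 64 species, 16
hibernators — on a seeded pure-birth tree scaled to unit height.
Hibernators receive a planting-rate multiplier (1.6) and a strength
increment (+0.25 over a 0.6 baseline); these effect sizes are our
choice of a clearly detectable but not saturated contrast (the real
genomes' effect sizes are not derivable from published summaries), and
hibernator status is assigned to random tips.  The cohort's genomes use
25 genes per species, which keeps a 20-replicate power experiment
inside a few minutes of CPU while leaving per-species affinity
estimates noisy enough to be non-trivial.

The generators deliberately do **not** emulate: base-composition
heterogeneity (isochores, CpG islands), repeats, isoform diversity,
overlapping genes, alignment error, or phylogenetically clustered trait
assignment.  Passing tests therefore demonstrate correctness of the
*methods* under the stated model, not robustness to every property of
real genomes.

## Numerical choices and degenerate inputs

* PWM DP and scanning share one integer lattice; probabilities sum to
  1 within $10^{-9}$ by construction.
* The codon likelihood uses the symmetrized eigendecomposition of the
  reversible generator; transition matrices are clamped at 0 and
  partials rescaled per pattern, so likelihoods never underflow on the
  tree sizes the package targets (≤ ~64 taxa).
* $\omega$ is bounded to $[10^{-4}, 99]$, $\kappa$ to $[0.05, 99]$,
  branch lengths to $[10^{-6}, 20]$; a slightly negative LRT statistic
  (within $10^{-3}$) is truncated to zero, anything worse raises an
  error pointing at optimizer failure.
* Degenerate inputs raise errors rather than silently returning:
  zero-variance t-tests with unequal means, constant traits in the
  ANOVA, a constant binary trait in the threshold model, `n_sim = 0`,
  genomes whose intergenic gaps cannot hold the upstream window.
* The threshold-trait simulator resamples (up to 100 incremented
  sub-seeds) when a draw yields a constant binary trait.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run everything from scratch,
at sizes chosen to make each check statistically meaningful at
interactive cost: exhaustive PWM enumeration up to width 6 (twenty
matrices); ten 1-Mb background scans for the false-positive
calibration; 3- and 4-taxon brute-force likelihood oracles at
tolerance $10^{-8}$; a 16-taxon × 500-codon recovery of $\omega = 0.05$;
200 null replicates (8 taxa × 150 codons) for LRT calibration; 500
Brownian-null replicates (64 tips, 200 simulations each) for the ANOVA
type-I error; 50 replicates for threshold-model coverage at $r = 0$;
and 20 replicate 64-species cohorts for the hibernator contrast.

## Known limitations

* The one-ratio/two-ratio optimizer is coordinate ascent, not a joint
  Newton method; on pathological likelihood surfaces it can need many
  rounds (free-ratio on larger trees is the slowest case and reports
  non-convergence rather than pretending).
* Absolute log-likelihoods of published branch-model tables depend on
  unpublished run settings (codon-frequency model, data cleaning,
  initial values) and are not reproducible bit-for-bit from printed
  summaries; the package therefore validates the arithmetic relations
  between models (the $2\Delta\ell$ statistics and their $\chi^2$
  p-values) and the recovery of known parameters from simulated data.
* The threshold-model sampler mixes slowly when the binary trait is
  nearly constant or the tree is very unbalanced; the result object
  carries the proposal acceptance rate and a mixing warning instead of
  failing.
* On deeply hierarchical trees a single simulated dataset carries
  limited information about the liability-value correlation, so
  posterior means scatter widely around the simulating value from one
  realization to the next (the unit suite checks instead that our
  sampler agrees with the independent `phytools::threshBayes`
  implementation on identical data).  Point-recovery claims should be
  judged across replicate datasets.
* Peak classification is midpoint-based by design; bases of a wide
  peak outside the midpoint's feature do not influence its class.
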