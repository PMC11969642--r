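---
title: "Quantifying variation between collagen peptide mass fingerprints"
author: "pmfvar developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying variation between collagen peptide mass fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfvar)
```

## Scope and model

`pmfvar` treats a collagen peptide mass fingerprint (PMF) as a sparse
vector of peak intensities indexed by m/z, and a study as a collection of
such vectors with taxonomic factor labels (family, genus, dataset). All
downstream statistics are rank- or composition-based, chosen for the
realities of MALDI-ToF data: absolute intensities are not comparable
between spots, peak detection is stochastic, and fingerprints of related
taxa share many peaks while differing in a minority.

The analysis chain is:

1. peak lists → per-spectrum normalization (total intensity 100) → greedy
   m/z alignment into a samples × features matrix;
2. non-biological feature removal (minimum m/z, mass-defect rule);
3. square-root transform (intensity mode) or binarization;
4. Bray-Curtis dissimilarity, ANOSIM, SIMPER, nMDS;
5. information-gain marker selection and classification (binary mode);
6. correlation of pairwise ANOSIM R with sequence divergence and
   evolutionary distance (ED, Mya).

## Statistics

**Bray-Curtis.** For non-negative fingerprints $x, y$ over features $f$,
$d(x,y) = 100\,\sum_f |x_f-y_f| \,/\, \sum_f (x_f+y_f)$, with similarity
$100 - d$. The 0-100 scale matches how group similarity scores are
conventionally printed. A square-root transform is applied to intensity
matrices first, damping dominant peaks; whether to normalize each
spectrum to a common total beforehand is a package decision (default on,
configurable) since absolute MALDI intensities carry no cross-spot
meaning.

**ANOSIM.** All $n(n-1)/2$ pairwise dissimilarities are ranked (midranks
for ties — ties are ubiquitous with binary data); with $r_B$ and $r_W$
the mean between- and within-group ranks,
$$R = \frac{r_B - r_W}{c}, \qquad c = \frac{n(n-1)}{4}.$$
$R$ is 0 when groups are indistinguishable and reaches 1 exactly when
every between-group dissimilarity exceeds every within-group one; being
rank-based it is invariant under monotone transforms of $d$. Significance
is by label permutation, sampled uniformly excluding the identity, with
$\mathrm{sig}\% = 100\,(n_{\ge}+1)/(n_{perm}+1)$ — the convention under
which 44 exceedances out of 999 permutations print as 4.5%. Pairwise
tests run on the two-group sub-matrix and report the count of distinct
label arrangements $\binom{n_1+n_2}{n_1}$, or a `"very large"` sentinel
above $10^9$. The global multi-group statistic is the default headline
number; the mean of pairwise R values is also available
(`mean_family_R_table()`) since either convention appears in practice.

**SIMPER.** For a within-group pair $(j,k)$, feature $i$ contributes
$100 \cdot 2\min(x_{ij},x_{ik}) / \sum_f (x_{fj}+x_{fk})$ to the pair's
similarity; between groups the contribution is
$100 \cdot |x_{ij}-x_{ik}| / \sum_f (x_{fj}+x_{fk})$. Averaging over
pairs gives per-feature contributions that sum *exactly* to the group's
mean Bray-Curtis similarity (or the pair of groups' mean dissimilarity) —
a conservation identity the test suite asserts to $10^{-9}$ relative.
Features are reported with contribution %, cumulative %, and a
contribution/SD ratio (∞ when the across-pair SD is 0);
`top_contributors()` returns the minimal prefix reaching a cumulative
cutoff (e.g. 70%), breaking contribution ties by ascending m/z.

**nMDS.** Ordination minimizes Kruskal stress-1 by iterative monotone
regression. The engine is `vegan::monoMDS` (global model); `pmfvar`
contributes the restart protocol — one metric (principal-coordinate)
start plus `n_restarts - 1` random starts, best stress kept — and seeds
it deterministically. Coordinates are centred at the origin; only
coordinates and stress are emitted, plotting is left to the user.

**Markers.** On a binary matrix, each taxon is scored one-vs-rest: a
feature's information gain is $H(y) - \sum_v \frac{n_v}{n} H(y \mid x=v)$
in bits (ID3). Features with gain ≥ 0.3 bits (default) are kept, at most
10 per taxon, each with its expected presence state (the state enriched
in the taxon). Classification requires ≥ 80% of a taxon's markers to
agree; zero or multiple matching taxa yield `Unclassified`, biasing
errors toward abstention rather than false positives. These
hyperparameters are package defaults — the approach is a principled
re-implementation of entropic dichotomous marker selection, not a port of
any particular tool, and exact reproduction of published sensitivity
figures is not promised. "False negative" pools wrong-taxon and
`Unclassified` outcomes from the true taxon's perspective.

**Sequence layer.** `identity_metrics()` skips positions gapped in both
sequences and counts single-gap positions as differences. Predicted
amino-acid change applies the per-chain rates COL1A1 = 0.7, COL1A2 = 0.9,
COL1A3 = 1.0 linearly to ED. The literature does not pin down the time
unit of these rates, so `predicted_change()` carries an explicit
`time_scale` multiplier (default 1, i.e. changes per Mya) recorded in
every record; ED is taken as the divergence time itself, not doubled for
the two lineages. Because both residue- and nucleotide-level differences
appear in published correlation figures, the sequence layer computes its
metrics from whatever alignment it is given and leaves the choice of
molecule to the user. The bundled global aligner (match +1, mismatch −1,
gap −2) is for toy inputs only; curated alignments should be supplied for
real chains. `fit_linear()` is ordinary least squares with $r^2 = r^2_{
Pearson}$; `welch_t()` is the unequal-variance t-test with Satterthwaite
degrees of freedom.

## The synthetic-data generator

`simulate_pmf_study()` emulates the structure of multi-family collagen
PMF datasets:

* **Taxonomy** — a random ultrametric coalescent tree rescaled to a
  stated depth in Mya; pairwise ED is half the patristic distance.
* **Peptides** — a root fingerprint of 45 masses (default) drawn in
  900-3500 Da with tryptic mass defects (fractional mass
  $\approx 4.95\times10^{-4}\,m/z$), split across the three collagen
  chains. Along each branch, substitution events arrive as a Poisson
  process at rate $0.5 \cdot \text{rate}_c \cdot \text{scale} \cdot
  \ell$ per chain, so the expected substitution count separating two
  leaves equals $\text{rate}_c \cdot \text{scale} \cdot \mathrm{ED}$ —
  the same convention as `predicted_change()`. Each event rewrites one
  non-glycine residue of the chain (every third residue stays Gly,
  preserving the collagen motif) and, when the position falls inside an
  observable peptide's residue span, shifts that peptide's mass by the
  corresponding residue mass difference (near-isobaric Leu/Ile
  exchanges, invisible at PMF precision, are excluded). Peptide spans
  cover only ~30% of each 1014-residue chain, mirroring partial tryptic
  coverage; without this, fingerprints saturate (all pairwise R = 1) at
  moderate depths and the ED-R relation degenerates.
* **Markers** — each leaf receives 3 planted taxon-unique masses kept
  > 1 Da from every evolved mass, so each marker aligns into a feature of
  exactly one taxon (the ground-truth invariant the marker-recovery tests
  rely on).
* **Spectra** — each of 10 individuals per leaf observes each leaf
  peptide with probability `detection_prob`, at log-normal intensity with
  coefficient of variation `intensity_cv` around a per-peptide base;
  plus uniform-m/z chemical-noise peaks and ever-present matrix peaks at
  1060.1 Da (defect ≈ 0.1, removed downstream by the defect rule).
* **Sequences** — the same event stream yields gap-free aligned chain
  sequences per leaf, coupling sequence count-difference to fingerprint
  divergence; pairwise true substitution counts (total and per chain) are
  recorded as ground truth.

**Calibration of defaults.** Where the emulated studies state no value,
defaults were fixed once, before the test suite was frozen:
`n_individuals = 10` matches typical per-family sample sizes in published
ZooMS datasets; the noise triple `detection_prob = 0.6`,
`intensity_cv = 1`, `n_noise_peaks = 30` was chosen so simulated
within-group Bray-Curtis similarity lands near 40, inside the 20-42 band
real fingerprint datasets exhibit (fish at the low end, mammals and
amphibians at the high end). The `"fish"` preset (divergence scale 2,
detection 0.7) and `"mammal"` preset (1, 0.9) reproduce the *direction*
of the fish-vs-mammal within-group similarity contrast, not any printed
magnitude. Trypsin digestion, isotope envelopes, hydroxyproline and
detector physics are not modelled: the generator produces peak lists, not
physics.

**What a green test establishes.** Synthetic data shares the *structure*
of real studies (taxon-clustered peaks, divergence-coupled mass shifts,
contaminants) but none of their biology — no PTMs, no real digestion
chemistry, no database-matched masses. Green pipeline tests therefore
establish correctness of the statistics and the plumbing, and qualitative
reproduction of the published phenomena (ED-R correlation, noise-driven
similarity loss, marker recoverability); they do not validate taxonomic
assignments of real spectra. Reproducing published real-data values
(e.g. a global fish R of 0.809) additionally requires the original
deposited peak lists and the original peak-picking parameters, which are
external to this package.

## Numerical choices

* Alignment tolerance 0.3 Da, constant (not ppm) — a typical MALDI-ToF
  PMF bin width; greedy merge ascending in m/z against the feature's
  running intensity-weighted mean, followed by consolidation passes until
  no two feature references are within tolerance (this makes alignment
  idempotent). A sample contributing several peaks to a feature has them
  summed, conserving row totals.
* Mass-defect filter: expected defect $4.95\times10^{-4} \cdot m/z$
  (the averagine peptide defect), circular deviation tolerance ±0.25, so
  the rule stays correct above m/z 2000 where peptide defects approach 1.
  Both constants configurable; minimum m/z default 900.
* Peak picking: moving-average smoothing (half-window 20 points),
  SNIP-style iterative baseline (100 iterations), noise estimated as the
  MAD of the *unsmoothed* baseline-corrected trace so the SNR threshold
  refers to point noise; local maxima with height ≥ SNR × noise are
  reported. Output is invariant to uniform intensity scaling. The
  original studies' per-dataset half-window/SNR values live in their
  supplementary material, so real-data use requires user-supplied
  parameters.
* ANOSIM permutations are sampled with replacement, identity excluded;
  degenerate all-equal dissimilarity matrices return R = 0 with a
  warning. Seeds are mandatory at the CLI; per-pair streams in
  `pairwise_anosim()` derive from the base seed.
* nMDS: 50 restarts, max 300 iterations, stress-ratio convergence at
  $1-10^{-6}$.
* All-zero samples after filtering are dropped with a warning; all-zero
  rows elsewhere are retained with a warning (binarization), and all-zero
  feature columns are dropped at matrix construction.

## Known limitations

* Bruker raw formats, recalibration, deisotoping and adduct libraries
  beyond the defect rule are out of scope; inputs are picked peak lists
  (or simple profile traces) plus a metadata table.
* The classifier is deliberately conservative; sensitivity on noisy data
  is traded for a near-zero false-positive rate.
* Divergence times are user-supplied (a CSV of taxon pairs in Mya);
  no external database querying is performed.
* The ED-R relation in both real and simulated data is noisy and
  saturates for deep splits — hence the provided `filter_by_ed()` cutoff
  (e.g. 150 Mya) before linear fitting.
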