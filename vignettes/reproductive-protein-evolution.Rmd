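---
title: "Models and methods: reproductive protein evolution in a four-taxon phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Reproductive proteins evolve unusually fast in many animal lineages, but the
evidence in flowering plants is thinner and entangled with three confounders:
mating system (self-compatible lineages have smaller effective population
sizes and therefore less efficient selection), haploid expression (pollen and
ovule gametophytes expose alleles directly to selection), and the well-known
negative correlation between expression breadth/level and protein evolutionary
rate. `repevol` implements a complete analysis for a four-species *Solanum*
system — two self-compatible (SC) species (*S. lycopersicum*,
*S. pimpinellifolium*) and two self-incompatible (SI) species (*S. pennellii*,
*S. habrochaites*) on the fixed unrooted topology
`((lycopersicum, pimpinellifolium), (pennellii, habrochaites))` — that
separates these strands:

1. classify genes by tissue-level expression (reproductive, vegetative,
   general; tissue-specific; gametophytic vs sporophytic),
2. estimate per-locus and per-class dN/dS under codon substitution models,
3. compare classes with a statistics layer built for heavily skewed rate
   distributions (gamma GLMs, exact tests on the proportion of adaptively
   evolving loci, a bootstrap null for lineage contrasts).

A ground-truthed simulator generates both input layers, so every estimator in
the package is validated against known truth.

# Codon substitution model

The engine is a Goldman–Yang-style (GY94) Markov model on the 61 sense codons.
For codons $i \ne j$ differing at exactly one nucleotide position,

$$q_{ij} = \begin{cases}
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}$$

with $q_{ij} = 0$ for multi-nucleotide changes. Stationary frequencies
$\pi$ default to F3×4 (products of position-specific nucleotide frequencies
estimated from the data, stop codons removed and renormalized, with a 0.5
pseudocount per nucleotide so short alignments keep strictly positive
frequencies); F61-style custom frequencies or uniform frequencies can be
supplied. Each branch-class generator is rescaled so one unit of branch
length equals one expected substitution per codon at that class's fitted
parameters — the convention that makes branch lengths comparable across
fits.

Likelihoods are computed by Felsenstein pruning over the unrooted four-taxon
tree, with the root placed on the internal branch and root states weighted by
$\pi$; reversibility makes the value invariant to root placement (tested
against an explicit mid-branch rooting). Since the generator is reversible,
$P(t) = e^{Qt}$ comes from the spectral decomposition of the
$\pi$-symmetrized generator. The pruning core and its gradient live in
compiled code (RcppArmadillo); branch-length derivatives are analytic
($dP/dt = U \,\mathrm{diag}(\lambda e^{\lambda t})\, U^\top$ in the
symmetrized basis) while $\kappa$ and $\omega$ derivatives use forward
differences, caching one spectral decomposition per distinct
$(\kappa, \omega)$ pair.

## Fitted models

* **M0 (one-ratio)**: one $\omega$ shared by all five branches.
* **Two-ratio**: $\omega_{SC}$ vs a single $\omega$ for the SI tips plus the
  internal branch.
* **Three-ratio**: separate $\omega$ for SC tips, SI tips, and the internal
  branch.

All models co-estimate $\kappa$ and the five branch lengths by bounded
quasi-Newton (L-BFGS-B) with $\omega \in [10^{-4}, 99]$,
$\kappa \in [0.1, 50]$, branch lengths $\in [10^{-7}, 10]$. Optimization is
deterministic: a fixed $\omega$ start grid $\{0.1, 1, 2\}$ (branch lengths
start from codon p-distances, $\kappa$ from 2), a coarse pass from each
start, then a high-precision polish of the best optimum. A `fast` mode (one
medium-precision pass) serves warm-started refits such as bootstrap
replicates; `fixed` can pin $\kappa$ and branch lengths, which replicate
refits use because those are nuisance parameters shared across resamples of
the same loci. Nested fits warm-started from the null optimum guarantee the
likelihood ordering $\ell_{M0} \le \ell_{2R} \le \ell_{3R}$ up to optimizer
tolerance.

dN and dS are derived from the fitted tree length partitioned into
synonymous and nonsynonymous flux: with $\rho_S(\omega)$ the synonymous
share of substitution flux at the fitted parameters and $f_S = \rho_S(1)$
the mutational-opportunity share, $dS = T\rho_S / (3 f_S)$ and
$dN = T(1 - \rho_S) / (3(1 - f_S))$, which reproduces $dN/dS = \omega$
exactly for M0. Loci with all-identical sequences are flagged degenerate
($dN = dS = 0$, $\omega$ undefined) and excluded downstream, as are
non-convergent fits and $\omega > 10$ (almost always a symptom of no
synonymous signal).

An independent Nei–Gojobori (1986) pathway-counting estimator with
Jukes–Cantor correction (`ng86_counting()`) cross-checks the ML fits; in
its convention, mutational opportunities that create stop codons count as
nonsynonymous sites (so $S + N = 3L$) while pathways through stop codons
are discarded during difference counting.

# Expression classification

Counts are TPM-normalized per library
($\mathrm{TPM}_g = 10^6 (c_g/L_g) / \sum_j (c_j/L_j)$) and averaged across
replicates within each species × tissue. Eight tissues are used for
classification: five sporophytic-vegetative (leaf, root, stem, seed,
vegetative meristem), style (sporophytic but reproductive), and two
gametophytic (pollen, ovule). Missing species × tissue combinations (style
and pollen for *S. pimpinellifolium*) are masked — never imputed, never
voting.

All rules use two thresholds: *expressed* means TPM > 2, *trace* means
TPM < 0.5. Votes are cast per species, and a gene is labeled when at least
2 of the 3 fully sampled species agree:

* **RP**: ≥ 1 reproductive tissue expressed and every vegetative tissue at
  trace; **VG** is the mirror image; **GR**: at least one expressed tissue
  on each side.
* **Tissue-specific**: the focal tissue expressed and all seven others at
  trace.
* **Ploidy**: the same votes over the gametophytic/sporophytic partition
  (style is diploid, so style-only genes are sporophytic-exclusive);
  ovule- and pollen-specific genes are additionally split into
  tissue-only vs tissue-plus-sporophytic.

Two readings of the published rules were open. First, whether the expression
and trace conditions must hold in the *same* species: we require that
(within-species voting), because a gene expressed in ovule in one species
and silent in leaves of a different species is weak evidence of anything.
Second, the general class carries no explicit species rule; we apply the
same 2-of-3 vote for symmetry. Genes whose TPM values sit in the gray zone
[0.5, 2] can fail every rule and stay unclassified — that is by design of
the thresholds, not an error. Expression breadth counts tissues expressed
(TPM > 2) in *every* species with data for that tissue (0–8), and mean
expression averages TPM over the cells of the expressed domain only,
reusing the same > 2 threshold because the rules define "expressed" that
way everywhere else.

# Statistics layer

Per-locus $\omega$ distributions are strongly right-skewed, so class means
are compared with a gamma GLM with identity link (means stay on the
$\omega$ scale). Gamma support excludes zero while counting-style estimates
can be exactly zero; zeros are replaced by half the smallest positive
$\omega$ (count recorded on the fit object). Pairwise class contrasts use
the single-step (max-modulus) adjustment over the jointly normal contrast
vector — the GLM analogue of Tukey's test — with a compact letter display at
$\alpha = 0.05$; the quasi-Monte Carlo integration seed is pinned so tables
are reproducible. Proportions of loci with $\omega > 1$ are compared with
Pearson chi-square tests (no continuity correction by default) and
one-sided Fisher exact tests in the direction of first-group enrichment.

Because each gene class yields only one concatenated estimate per branch
class, the SC−SI contrast has no parametric error estimate. The bootstrap
null resamples loci from the generally expressed (GR) baseline (with
replacement by default — a resampling of loci, not sites), refits the
branch model on each replicate concatenation, and asks where the focal
class's observed SC−SI difference falls in the resulting distribution
(95% percentile interval). Replicates re-estimate the branch-class
$\omega$ values with $\kappa$ and branch lengths pinned at the pooled-GR
optimum: resamples of the same loci share those nuisance parameters, and
freeing them changes replicate differences by far less than the resampling
noise (a `per_replicate = "full"` option re-estimates everything).

The expression-level analysis regresses $\sqrt{\omega}$ on mean expression,
class, and their interaction by OLS, reporting the sequential ANOVA table
and per-class slopes with 95% CIs (via `emmeans`).

# Synthetic data

`simulate_alignment()` draws root codons from the stationary distribution
and evolves each branch by its exact transition matrix, with
branch-class-specific $\omega$. `simulate_counts()` plants expression
classes: expressed tissues at 30 TPM, silent tissues at 0.05 TPM — wide
margins around the 2/0.5 thresholds — then draws negative-binomial counts
(dispersion `size = 10` by default, emulating RNA-seq overdispersion;
Poisson is the `size` → ∞ limit) with means proportional to
TPM × gene length × library size. A small set of broadly expressed
background genes absorbs the rest of each library's one-million-TPM budget
so that planted values survive within-library normalization.
`simulate_study()` writes a complete bundle (per-locus FASTA, manifest,
counts, library metadata, ground truth, config) whose per-locus true
$\omega$ is lognormal around a class median — with `omega_sdlog` ≈ 0.7–0.8 a
realistic minority of reproductive loci genuinely exceeds 1, mirroring the
few-percent adaptive fractions seen in real data.

Default tree lengths (SC tips 0.002, SI tips 0.02, internal 0.01
substitutions/codon) echo the system's strong branch asymmetry and are
illustrative, not estimates. At those lengths a single locus carries very
little signal — which is faithful to the real system, where per-branch
rates are only estimable from concatenations. Validation simulations
therefore use scaled-up trees that keep the SC-short/SI-long shape:
(0.05, 0.05, 0.1, 0.1, 0.08) for recovery and calibration checks, and
(0.02, 0.02, 0.06, 0.06, 0.04) for the bootstrap studies.

## What the simulations do and do not show

The generator matches the analysis model (GY94 columns i.i.d., NB counts
with planted means). Passing recovery tests therefore demonstrates correct
inference under the assumed model — not robustness to misalignment, indel
errors, isoform switching, selection heterogeneity among sites, or
expression batch effects, none of which are simulated. Alignment cleaning
(gap/stop/ambiguity columns dropped, the > 200 bp length filter) is
exercised on constructed fixtures instead.

## Validation scales

The test suite runs, under fixed seeds: parameter recovery (30 replicates ×
500 codons per true $\omega \in \{0.1, 0.5, 1.0\}$, median within ±15%);
branch-model sign recovery (100 replicates of 50-locus concatenations,
$\omega_{SC} = 0.4$ vs $\omega_{SI} = 0.2$, ≥ 95 correct); LRT null
calibration (100 null datasets of 300 codons, 5% rejection within
[2%, 12%]); bootstrap
calibration (20 meta-replicates of 100 bootstrap replicates × 50 loci ×
100 codons, baseline pool of 150 loci and a 100-locus focal set, ≥ 90%
coverage) and power (+0.15 on $\omega_{SC}$ in the focal set, 12
meta-replicates, ≥ 80% detection); classification recovery (1000 planted
genes at dispersion 10, ≥ 95%). Meta-replicate counts for the bootstrap
studies are modest because each meta-replicate is a full bootstrap study;
the thresholds are unchanged from the per-study criteria. The focal set is
simulated larger than the resample size so its estimate is at least as
precise as one bootstrap replicate — the regime the method is designed
for, where the baseline pool dwarfs the resample.

# Known limitations

* Site-homogeneous models only: no among-site $\omega$ variation
  (M1a/M2a), no branch-site tests, no tree search — the topology is fixed
  by design.
* The bootstrap null inherits the usual percentile-interval caveats at
  small replicate counts; 1000 replicates (the default) are recommended
  for real analyses.
* Gamma-GLM zero handling is a pragmatic imputation; results are
  insensitive to the substitute value in our checks, but a two-part model
  would be the principled alternative.
* NG86 stop-codon conventions differ slightly among published
  implementations; ours is documented above and used only as a
  cross-check.
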