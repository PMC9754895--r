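---
title: "Divergence landscapes, genomic islands, and environmental association with divscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence landscapes, genomic islands, and environmental association with divscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

divscan implements the bespoke computations of a two-species population
genomic divergence analysis as a tested, reusable pipeline. This vignette is
the package's own account of the models it fits, the choices that were
genuinely open, and what its synthetic data can and cannot tell you about
real data.

## The estimators

**Per-site variance components.** Differentiation is measured with the Weir
& Cockerham (1984) estimator for two populations of unequal size. For each
biallelic site we compute the among-population component $a$ and the total
$a+b+c$ from allele frequencies, observed heterozygosity and per-site
non-missing sample sizes. A window's $F_{ST}$ is the ratio of sums
$\sum a / \sum (a+b+c)$ — the "weighted" convention used by the common VCF
tooling. Negative site components are informative about sampling noise and
are retained; a site where either species has fewer than two non-missing
diploids is skipped for all statistics.

**Diversity and divergence.** Within-species diversity uses the unbiased
per-site heterozygosity $\frac{n}{n-1} 2\hat p(1-\hat p)$ on allele counts
$n$, summed over sites and divided by the full window length, so
monomorphic positions count as zero difference. Between-species divergence
is $D_{XY} = \sum_s [\hat p_A(1-\hat p_B) + \hat p_B(1-\hat p_A)]/L$, which
equals the average per-bp difference over all inter-species pairs of
sequences; computing it from frequencies rather than phased haplotypes is
exact for this quantity (a property the test suite checks against
brute-force pair enumeration). The denominator choice (window length, not
number of variable sites) puts the values on the per-bp scale on which
genome means are conventionally reported.

**Recombination.** The population-scaled recombination rate
$\rho = 4N_e r$ per bp comes from a moment inversion rather than a
likelihood method: among window SNPs with pooled minor-allele frequency at
least 0.1, we take the mean pairwise dosage $r^2$ (Rogers–Huff style, which
needs no phase), subtract the finite-sample expectation $1/(2n)$, and solve
$\bar r^2 = 1/(2 + \rho \bar d)$ at the mean pairwise distance $\bar d$.
Corrected $\bar r^2 \ge 0.5$ clamps $\rho$ to 0; non-positive corrected
$\bar r^2$ means no detectable LD and yields a missing value rather than an
arbitrarily large rate. This is a deliberate stand-in for regression-based
external estimators: it preserves the ordering of strong- versus weak-LD
regions (what the island comparisons need), not absolute calibration.

**Windows.** The genome is scanned in 20-kb windows advanced 5 kb, 1-based
inclusive coordinates; windows with fewer than 10 usable SNPs are emitted
but excluded from every downstream comparison. Both conventions are
parameters of `window_stats()`.

## The island scan

Candidates are the top 1% of analyzed windows by $F_{ST}$ (ties at the
cutoff all included). Each candidate is compared with a null formed by
drawing the same number of sites, uniformly without replacement, from the
genome-wide pool of per-site variance components and recombining them as a
ratio of sums; the empirical p uses the add-one convention
$p = (\#\{null \ge obs\}+1)/(n_{perm}+1)$. Because the resampling unit was
genuinely open (raw per-site ratios versus variance components), both are
implemented; components-recombined-as-ratio-of-sums is the default since it
reproduces exactly the statistic being tested. Benjamini–Hochberg q-values
are computed over the candidate set only — p-values exist only for
candidates — and outliers (q < 0.01) that overlap or are book-ended merge
into island regions. The default of 10,000 permutations per window makes
the smallest achievable p ≈ 1e-4, ample for an FDR threshold of 0.01 over
tens of candidates; the millions-scale setting used on full genomes is
reachable through the same argument.

Island-versus-background contrasts use two-sided rank-sum tests on window
$\pi$, $D_{XY}$, $\rho$ and $\rho/\pi$ (islands = non-excluded windows
overlapping a merged region), plus a chi-square goodness-of-fit of
outlier-window counts per chromosome against the analyzed-window totals.
Identical constant samples return p = 1 rather than the NaN a rank-sum
statistic with zero variance would give.

## Copy-number differentiation

Gene copy numbers are overlap-length-weighted means of segment copy numbers
with uncovered gene bp at the diploid baseline 2; genes never touched by a
segment stay at baseline and are excluded from the ranked universe.
$V_{ST} = [V_{total} - (V_A N_A + V_B N_B)/N_{total}]/V_{total}$ uses
population variances (divisor $N$): the formula weights the within-group
variances by group sizes and normalizes by $N_{total}$, which is only
consistent if the variances are population variances; a flag switches to
$N-1$ for sensitivity analysis. The top 5% of genes by $V_{ST}$ are
re-tested by permuting species labels (group sizes preserved, add-one p,
$\ge$ comparison); a gene is copy-number differentiated if it is an outlier
and $p \le 0.01$. Note the procedure's intrinsic false-call budget: the
marginal permutation p is uniform under the null, so about
$\alpha \times$ (number of ranked genes) null genes pass both filters —
the calibration test asserts exactly that bound, not a rate conditional on
the top-5% selection (which is biased low by construction).

## The selection scan

For each gene and focal species we count SNPs polymorphic within the
species ($N_1$) and fixed between species ($N_2$, per-site WC ratio
$\ge 0.95$; negative or undefined ratios count as below threshold), and
compare the gene's $N_1\!:\!N_2$ against the genome margins by Pearson
chi-square (1 df, no continuity correction, warning when an expected count
drops below 5). The genome margins exclude the focal gene's own counts by
default, avoiding self-comparison; with genome-scale margins the effect is
negligible, and a flag restores the pooled margins. The test runs once per
focal species, with a pooled mode behind a flag for designs that count
polymorphism in either species. A candidate must additionally have more than one
nonsynonymous fixed site. Because sites within a gene are linked, the
chi-square is approximate; on neutral synthetic genomes the realized
fraction of genes at $p \le 0.01$ is bounded at 3% in the test suite rather
than the nominal 1%.

## Environmental association

Predictor screening removes autocorrelation greedily: while any pair has
$|r| \ge 0.7$, drop the predictor with the most such partners (ties by
larger mean absolute correlation, then lexicographic), so the result is
deterministic. LD pruning slides a 20-kb window advanced two markers at a
time and removes the later-position member of any still-kept pair with
dosage $r^2 > 0.4$ — the marker-step reading of the common PLINK-style
phrase.

The RDA itself is ordinary multivariate least squares of the mean-imputed,
column-centered dosage (or copy-number) matrix on the standardized
predictors, followed by an SVD of the fitted values: constrained
eigenvalues are squared singular values over $n-1$, the proportion of
response variance explained is their sum over the total, and variant
scores are right singular vectors scaled by singular values. Dosages are
centered but not standardized by default (a flag standardizes), and
missing dosages are mean-imputed — both are points standard ordination practice settles
differently from package to package, so they are explicit flags here. Axis significance is a permutation test of the axis eigenvalue
under row permutation of the predictor matrix, tested sequentially and
stopping at the first non-significant axis; this marginal test is simpler
than the sequential conditioning some ordination packages apply, a
deviation we accept for transparency (an independent RDA implementation is
used as a cross-check of the fit itself in the test suite). Outliers load
beyond 3 SD (strict inequality; two-tailed normal p = .0027) on any
significant axis; sign flips of axes cannot change calls because only
$|z|$ enters. Each outlier is assigned the predictor with the largest
absolute Pearson correlation to its dosages, with $|r| > 0.6$ flagged
strongly associated — assignment labels the dominant predictor, it never
deletes outliers.

Mantel tests operate at the population level: genetic distance is
$F_{ST}/(1-F_{ST})$ from pairwise Weir–Cockerham population $F_{ST}$ over a
SNP set, geographic distance is haversine on the 6371-km sphere, and
environmental distance is Euclidean on population means of standardized
predictors. For up to 7 populations the permutation distribution is
enumerated exhaustively (p is then the exact fraction of permutations with
$r \ge r_{obs}$, identity included); beyond that, seeded random
permutations with the add-one convention. Pairs at $F_{ST} = 1$ have
infinite linearized distance and are excluded with a warning.

## The synthetic study design

The generator emulates the sampled design the pipeline targets: 26 + 14
diploids from 12 + 4 populations in two latitude bands, four 1-Mb
chromosomes at 0.002 SNPs/bp by default. Site frequencies follow the
Balding–Nichols model — ancestral frequency from Beta(0.8, 0.8) truncated
to [0.05, 0.95], species frequencies from
$\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with $F = 0.2$ in the background
and $0.9$ inside planted islands. The Beta model was chosen over coalescent
simulation because its expected differentiation is known in closed form
(the Hudson ratio-of-averages $F_{ST}$ of the model equals $F$; verified by
Monte Carlo in the test suite), which makes parameter-recovery tests sharp.

Linkage is injected by founder-haplotype blocks rather than genealogies:
within each 20-kb block, haplotypes are drawn from a pool of K founders
(K = 100 in the background, 6 inside islands; `Inf` gives independent
sites). Small K simultaneously raises realized differentiation variance
and pairwise $r^2$, so islands acquire the low-ρ signature. The per-SNP
truth frequency is the realized founder-pool frequency, so sample allele
frequencies converge to truth as samples grow.

Three structural features are planted deliberately. First, a
fixed-difference mass: 12.8% of background sites are fixed between the
species, matching the share such sites contribute at study scale and
giving the site-$F_{ST}$ distribution its U shape — pure Balding–Nichols
at $F = 0.2$ produces essentially no sample-level fixed differences at
these sample sizes, so the mass must be explicit. Second, island SNP
thinning (half density by default): under Balding–Nichols the expected
per-site $D_{XY}$ is independent of $F$, so elevated-$F$ islands alone
would not show the reduced per-bp $\pi$ and $D_{XY}$ that linked selection
produces; removing segregating sites is exactly how linked selection
manifests, and thinning reproduces the joint reduction. Third, planted
features for recovery tests: selection-target genes in which sites are
fixed differences with probability 0.8 (a nearly completed local sweep)
and nonsynonymous counts of at least 2; copy-number differentiated genes
with species means 2 versus 4 and sparse background copy-number noise
(5% carrier rate — sparse noise matches real CNV data and keeps per-gene
permutation nulls honest); and environment-associated SNPs whose dosages
discretize a latent variable loading 0.95 on standardized annual
precipitation (realized dosage–AP correlation ≈ 0.85–0.9). Annual
precipitation is separated between the species by 3 within-species SDs;
minimum temperature, diurnal range and subsoil pH are separated more
mildly (1–1.3 SDs), calibrated so that no pair of distinct predictors
crosses the 0.7 autocorrelation threshold by sampling noise at n = 40; an
eighth predictor is built from maximum temperature at $r \approx 0.9$
specifically to exercise the filter. All randomness flows from one seed
through fixed substream offsets, and identical configurations produce
byte-identical output files.

**What passing tests do and do not show.** The generator has no demography
(no bottlenecks, expansions or gene-flow pulses), no mutation-model
realism, no within-species spatial structure, and its LD is blockwise
rather than genealogical. Recovery results therefore demonstrate that the
estimators and calling procedures are correct and calibrated under a
controlled model — not that they would achieve the same power on real
resequencing data. Two desk-scale artifacts are worth knowing: with only
2–3 diploids per population, pairwise population $F_{ST}$ on small,
highly differentiated SNP sets approaches 1, so linearized $F_{ST}$
explodes and the associated-set Mantel correlation is unstable; and
because every population inherits its species' single allele-frequency
draw, neutral SNP sets also separate the species and hence show
isolation-by-distance signal that real neutral intergenic sets need not
show.

## Numerical choices and problem sizes

Permutation p-values all use the add-one convention with a $\ge$
comparison and a 1e-12 epsilon against floating-point jitter when a draw
reproduces the observed set. Ties at ranking cutoffs (top-1% windows,
top-5% genes) are all included. BH q-values come from `stats::p.adjust`;
rank-sum and chi-square tests from `stats`; haversine distances from
geosphere with r = 6371 km. Degenerate inputs have defined behaviour:
monomorphic sites contribute zero components, zero total copy-number
variance makes $V_{ST}$ undefined and excluded, constant predictors are
dropped with a warning, zero loading SD yields no outliers on that axis.

The test suite and the acceptance script run the recovery experiments at
deliberately modest sizes — 2 × 1.2-Mb genomes over 20 seeds for the
island scan (10,000 permutations per candidate window), 20 seeds of
100-gene genomes for selection power and neutral calibration, 400 null
fits for the RDA axis test's type-I error, 40 seeds for planted-predictor
assignment — chosen as the smallest designs at which the binomial error of
the measured rates is comfortably inside the asserted bounds.
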