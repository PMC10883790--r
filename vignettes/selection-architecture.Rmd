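---
title: "Mapping selection architecture from temporally stratified genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping selection architecture from temporally stratified genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selarch)
```

## The problem

Directional selection reshapes a genome through three routes: hard sweeps
(one beneficial haplotype rises quickly and erases linked variation), soft
sweeps (several haplotypes rise together), and polygenic selection (many
small, consistent allele-frequency nudges at trait loci). The first two
leave classical signatures on linked neutral variation; the third does not,
which is what makes it hard to map. In managed populations — livestock being
the canonical case — genotypes are collected continuously across birth
cohorts, so the time axis itself can be used as a mapping variable.

selarch implements this combined analysis: a mixed-model scan that regresses
SNP genotype against a *generation proxy* (Generation Proxy Selection
Mapping, GPSM), plus haplotype-based (nSL), composite (mu), and
site-frequency-spectrum (Tajima's D) sweep scans, and the synthesis layer
that contrasts what the methods find.

## The GPSM model

The dependent variable is not a phenotype but the generation proxy

$$y_i = \text{(reference date)} - \text{(birth date of } i\text{)}$$

in decimal years. Populations with overlapping generations have no integer
generation number, which is precisely why a continuous proxy is used. The
per-SNP model is

$$y = \mu + b\,x + a + \epsilon,\qquad
  a \sim N(0,\, G\sigma_g^2),\quad \epsilon \sim N(0,\, I\sigma_e^2),$$

where $x$ is the SNP dosage and $G$ the genomic relationship matrix built
from all markers with MAF > 0.01 (`compute_grm()`, the
$(x-2p)/\sqrt{2pq}$-standardized cross-product form). A nonzero $b$ means
the allele's frequency trends with birth date: ongoing directional
selection. Because $y$ counts years *before* the reference, a rising allele
has $b < 0$.

The polygenic term is the crux. Drift in a finite pedigreed population also
creates associations between genotype and birth year; those run through
kinship, and $G\sigma_g^2$ absorbs them. The per-SNP test measures trend
*beyond* what relatedness explains — this is what lets the scan separate
selection from drift, and the type-I calibration tests verify exactly that
property on drift-only simulations.

Variance components are estimated once under the null by REML
(`greml()`: average-information updates with an EM-like fallback,
step-halving, boundary projection at zero, convergence at
$|\Delta\ell| < 10^{-6}$ or 100 iterations). All solves run in the
eigenbasis of $G$, where $V = G\sigma_g^2 + I\sigma_e^2$ is diagonal; when
the GRM has fewer markers than samples the spectrum comes from a thin SVD of
the standardized marker matrix and the zero-eigenvalue block is handled
analytically. The per-SNP scan (`mlma_scan()`) then reuses that one
factorization for every SNP: $\hat b = x'Py / x'Px$ with $P$ the REML
projection, Wald 1-df chi-square p-values. PVE
$= \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ with a delta-method standard error
from the inverse average-information matrix.

Two deliberate fidelity choices: the tested SNP is *not* removed from the
GRM (no leave-one-chromosome-out), and variance components are not
re-estimated per SNP. Both match how such scans are routinely run on a
whole-genome GRM; the cost is a known, mild proximal-contamination
attenuation of per-SNP signal, visible in the power studies.

### Proxy transformation

Commercial genotyping grows exponentially, so birth dates are extremely
left-skewed and the earliest-born individuals get inflated residuals.
`boxcox_transform()` fits the Box-Cox exponent by profile likelihood on a
\[-2, 2\] grid (step 0.01) with golden-section refinement, and the test
suite asserts the property that motivates it: BLUP residual skewness
(`blup_predict()`) shrinks after transformation on skewed-sampling
simulations.

### Thresholds and locus refinement

`threshold_ladder()` applies the standard ladder — nominal $p<10^{-5}$,
Bonferroni $0.05/m$ with $m$ the actual test count, genome-wide
$p < 5\times10^{-8}$, and Benjamini-Hochberg $q < 0.1$ and $q < 0.05$ — all
strict inequalities, BH applied across the whole run.

`cojo_select()` refines association peaks into independently associated
SNPs from summary statistics plus an individual-level LD reference:
stepwise forward selection starting at the smallest p-value, conditional
p-values by joint least squares on reference genotype cross-products (the
phenotypic sum of squares is imputed from each candidate's marginal $b$,
SE, and genotype variance; median across candidates), candidates with
$r^2 > 0.9$ to a selected SNP get conditional $p := 1$, and the final
report keeps SNPs with joint and marginal $p < 5\times10^{-8}$. Whether
the original analyses used stepwise selection or a single conditional pass
is ambiguous in the source tooling's documentation; stepwise is the cited
method's standard mode and is the default here, with `mode = "cond"`
(prune-then-one-joint-fit) selectable.

## Sweep statistics

**nSL** (`nsl_scan()`): for each focal SNP, haplotypes are split by allele;
within a class, each pair contributes the length — in segregating sites, the
statistic's defining, map-free distance unit — of the interval containing
the focal site over which the pair is identical. Raw
$nSL = \ln(SL_A/SL_D)$. Implementation is by group refinement (partition
haplotypes walking outward; identical pairs at step $t$ are
$\sum_g \binom{n_g}{2}$), which equals exhaustive pair enumeration — the
test suite checks exact equality on toy panels. Tract lengths are capped at
100 sites per side (configurable, flagged when hit). Scores are
standardized in 100 equal-width derived-allele-frequency bins; bins with
fewer than 2 SNPs merge with the nearest populated bin. Unpolarized panels
use REF/ALT classes and downstream windows take $|z|$, avoiding fabricated
ancestral states.

**Windows** (`spline_windows()`): instead of fixed windows, a cubic
smoothing spline (GCV-chosen smoothness) is fitted to $|z|$ against
position per chromosome and window breakpoints are placed at inflection
points (second-derivative sign changes). A curvature floor
($10^{-3}$ of the whole-chromosome bend scale) prevents numerically flat
fits from fragmenting into spurious windows, so a monotone profile yields
one whole-chromosome window. Windows partition the scored SNPs;
`call_outliers()` flags the top 0.5% of windows holding at least 3 SNPs
(ties at the cut all included, so degenerate all-equal inputs flag
everything — documented behavior).

**mu** (`mu_scan()`): 50-SNP windows sliding one SNP, on sites segregating
in the sample (a fixed site is not a variant, and the stretched span of
SNP-count windows across a swept region is precisely the diversity
signal). Three factors multiply:
$\mu_{VAR}$ = window bp span / (chromosome length × window SNP count);
$\mu_{SFS}$ = (singletons + derived-count-$(n-1)$ sites)/SNP count
(folded: minor-count-1 sites at half weight);
$\mu_{LD}$ = mean within-half $r^2$ (averaged over the two halves) divided
by mean cross-half $r^2$ ($+10^{-6}$, capped at $10^6$).
The composite is their product, assigned to the central SNP. Exact factor
constants only rescale the statistic monotonically and significance is a
rank quantile (top 0.05%), so the outlier set is invariant to them; the
forms above are this package's fixed definition. Overlapping significant
windows merge into loci when under 50 kb apart
(`merge_outlier_windows()`).

**Tajima's D** (`tajima_bins()`): fixed 100-kb bins,
$D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with textbook constants from
the sequence count; $D$ reported only when $S \ge 3$. Bins are
$[0, 10^5)$-style half-open internally, so a SNP at 1-based position
100,000 belongs to the first bin.

## Synthesis

`ld_profile()` computes $r^2$ between each lead SNP and all SNPs within
100 kb; profile sets are compared with a rank-based location test
(Kruskal-Wallis plus all-pairs Wilcoxon under Holm correction — chosen over
a parametric all-pairs HSD for robustness, switchable). `overlap_sets()`
matches loci across methods at strictly less than 50 kb.
`proximity_classes()` classifies each locus as within a gene, gene-proximal
(nearest boundary < 50 kb), or intergenic. `qtl_enrichment()` tests each
QTL class by a hypergeometric tail against the user-supplied QTL table as
its own background (external annotation databases are versioned and
proprietary; the background is therefore declared, not inferred), BH across
classes at FDR < 0.1, and reports the maximum single-chromosome hit count
per significant class because database redundancy often concentrates an
enrichment on one chromosome.

## The simulator and its study conditions

`simulate_population()` is a forward-in-time diploid simulator built to
emulate the data structure the scan assumes:

* **Overlapping generations.** Parents are drawn from all individuals in a
  2-10-year age window (configurable); a generation is therefore ~3.5-6
  years and no integer generation number exists — the reason a proxy is
  used at all.
* **Truncation selection** on a polygenic trait (effects $N(0, a^2)$ at a
  configurable number of loci, environmental noise scaled to the founder
  heritability, drawn once at birth), applied within sex — intense on
  males, mild on females, as in cattle breeding.
* **Sweeps** multiply a parent's sampling weight by $(1+s)$ per derived
  copy; **balancing selection** is heterozygote advantage with homozygote
  penalties split to give a chosen equilibrium frequency.
* **Recombination**: per-chromosome Poisson crossover counts with uniform
  breakpoints, no interference.
* **Founder haplotype structure.** Founder haplotypes are Li-Stephens-style
  mosaics of a small pool of ancestral haplotypes (default 24, ~10 mosaic
  breakpoints per Morgan). This gives the panel realistic LD and places
  selected alleles on few ancestral backgrounds, so hard sweeps are
  single-origin — without it (pool size 0: site-independent founders,
  linkage equilibrium) haplotype statistics have nothing to detect.
* **Recurrent mutation** at neutral sites (default $10^{-4}$ per site per
  gamete) keeps the sample SFS supplied with rare variants, as sequence
  data always are; selected loci are never mutated.
* **Left-skewed sampling**: genotyped counts per year proportional to
  $e^{k\cdot\mathrm{year}}$ (largest-remainder rounding), birth dates
  uniform within year, emitted as ISO dates.
* Everything flows from one seed; phased VCF (with the ancestral-allele
  INFO tag), metadata TSV, and a truth table (per-locus regime, parameters,
  realized founder/final frequencies, per-year trajectories of selected
  loci) are written by the pipeline.

What the generator does *not* emulate: genotyping or imputation error,
admixture between populations, pedigree recording, mutation at selected
sites, and genome-scale marker densities. Passing tests therefore
demonstrate the statistical machinery under the stated population
processes, not performance on any particular real dataset.

### Problem sizes used by the validation suite

These are the package's chosen desk-scale study conditions. The test suite
runs them at the replicate counts below; `scripts/acceptance.R` reruns the
same conditions with compact replicate counts (10 calibration replicates,
3 power replicates) and reports the measured quantities as JSON.

* **Type-I calibration**: drift-only populations, 300 founders, 550
  offspring/year over 20 years, 5 chromosomes × 1 Mb (1 Morgan each),
  5,000 SNPs, 2,000 genotyped samples with skew $k=0.3$; 20 replicates in
  the test suite. The fraction of SNPs at $p<0.05$ is compared with the
  95% binomial envelope (applied to the replicate mean, since LD makes
  per-replicate fractions over-dispersed relative to binomial), and no SNP
  should reach $5\times10^{-8}$.
* **Power**: intense modern selection — 1,000 founders, 1,500
  offspring/year, parent ages 2-5 (AI-era generation interval), top 5% of
  males / 50% of females retained, 100 trait loci with effect SD 0.25,
  founder $h^2 = 0.8$ (selection acts on accurate estimated breeding
  values, so the effective accuracy is high), 5,000 samples at skew 0.1.
  Success per replicate: Spearman correlation between realized $|\Delta p|$
  and $-\log_{10}p$ positive at $p<0.01$, and at least half of the
  top-decile trait loci (ranked by trajectory-slope $|\Delta p|$) at
  $p<10^{-5}$.
* **Sweep detection**: neutral-background population (no truncation), 500
  founders/offspring, 30 years, 1 Mb at 0.5 Morgan, 1,000 SNPs, a
  single-origin sweep ($s=1.5$ from frequency 0.05, fixing by sampling
  time), 100 sampled haplotypes; success when a top-0.05% mu window lies
  within 50 kb of the sweep site (the locus-matching tolerance used
  throughout the synthesis layer).
* **Balancing selection**: small population (80 founders/offspring) over
  80 years, 0.15 Morgan/Mb so linked variation stays associated with the
  balanced site, heterozygote advantage 1 at equilibrium 0.5; Tajima's D
  in the balanced 100-kb bin versus the chromosome background, paired
  one-sided Wilcoxon over 30 replicates.

The long horizons and small sizes for the sweep/balancing studies reflect
what those signatures need to arise at all in a forward simulation from
standing variation: balancing selection shows excess intermediate-frequency
diversity only after the background has drifted toward the frequency
extremes, and a sweep needs time to complete.

## Numerical choices and degenerate inputs

* GRM: monomorphic/low-MAF sites excluded with a count; negative
  eigenvalues from numerical noise floored at zero (magnitude recorded);
  an identity-like GRM (only the total variance identifiable) is flagged
  `degenerate`.
* GREML at a variance boundary projects to a small positive floor and sets
  `boundary`; non-convergence returns `converged = FALSE` and the scan
  refuses to run on it.
* Monomorphic test SNPs get $b=0$, $p=1$, and a flag.
* COJO: rank-deficient joint fits drop the most recent addition with a
  warning; the selected set is invariant to input record order
  (deterministic p-then-position ordering).
* Spline windows fall back to one whole-chromosome window when a
  chromosome has fewer than 10 scored SNPs, fewer than 4 distinct
  positions, or no appreciable curvature.
* Ties at outlier cuts are all included.
* All file coordinates follow their format conventions (VCF/GFF3 1-based
  closed, BED half-open); internal interval work is 0-based half-open with
  conversion only at I/O boundaries.

## Known limitations

* Single-GRM model only: no multiple variance components, dominance, or
  GxE; no leave-one-chromosome-out scan.
* COJO works from the same individual-level data used for the scan; pure
  summary-statistic input with an external LD panel is supported by
  construction but untested against reference implementations.
* The mu factor forms are this package's declared definition (see above);
  rank-based outlier calls are comparable, absolute mu values are not
  portable to other implementations.
* The simulator's recurrent-mutation model reuses the fixed site panel
  rather than an infinite-sites model; allele age and polarization are
  exact only up to that approximation.
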