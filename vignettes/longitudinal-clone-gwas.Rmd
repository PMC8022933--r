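---
title: "Multivariate mixed-model association analysis of longitudinal traits in clonally replicated trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate mixed-model association analysis of longitudinal traits in clonally replicated trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`clonescan` analyzes quantitative traits measured repeatedly over time on
*clonally replicated* progeny of a single outbred full-sib cross, planted
in a randomized complete block design (RCBD). The motivating setting is a
forest-tree height trial: each F1 seedling (a *clone*) is vegetatively
propagated into several cuttings, the cuttings are planted across blocks,
and every surviving tree is measured at a series of time points through
the growing season. Because all cuttings of a clone share one genome,
replication separates genetic from environmental variation far better
than single-tree designs, and the longitudinal trait vector carries
information a single-time-point analysis discards.

The tree-level model for the height of tree $k$ of clone $j$ in block $i$
at time point $t$ is

$$y_{ijkt} = \mu_t + B_{it} + M_{jt} + G_{jt} + e_{ijkt},$$

with fixed time-point means $\mu_t$, fixed block effects $B_{it}$ and
fixed SNP-genotype-class effects $M_{jt}$, each under a sum-to-zero
constraint; random clone polygenic effects $G_{jt}$; and residuals
$e_{ijkt}$. In matrix form $Y = BX + GZ + E$ with $Y$ the $m \times n$
matrix of heights ($m$ time points, $n$ trees), $X$ the $p \times n$
fixed-effect design, $Z$ the $c \times n$ clone incidence, and

$$\mathrm{cov}(\mathrm{Vec}(Y)) \;=\; Z'AZ \otimes V_G \;+\; I_n \otimes V_E,$$

where $A$ is the additive genetic relationship matrix among clones,
$V_G$ the $m \times m$ additive genetic covariance across time points and
$V_E$ the residual covariance. For full sibs of unrelated, non-inbred
parents, $A$ has ones on the diagonal and 0.5 elsewhere
(`build_fullsib_A()`); this pedigree form is used rather than a
marker-based kinship because most markers in such a cross segregate in
only two genotype classes, for which the usual three-class marker-kinship
estimators do not apply.

SNP effects are tested with the vectorized Wald statistic

$$F = \frac{1}{q}\,(M\,\mathrm{Vec}(B))'\,
  \big[M\,((X \otimes I_m)\,V^{-1}\,(X' \otimes I_m))^{-1} M'\big]^{-1}
  (M\,\mathrm{Vec}(B)),$$

with $q = m(g-1)$ numerator degrees of freedom ($g$ observed genotype
classes) and $m(n-p)$ denominator degrees of freedom, referred to the F
distribution. `Vec` stacks the $m \times p$ coefficient matrix column by
column, so time points run fastest within each coefficient; this ordering
is the single convention behind `snp_wald_hypothesis()`. The denominator
degrees of freedom are taken literally as $m(n-p)$; no Satterthwaite or
Kenward–Roger adjustment is applied. With the large $n$ of replicated
designs the F reference is essentially a scaled chi-square, so this
choice has negligible practical effect.

## Outbred segregation types and genotype QC

With two outbred, highly heterozygous parents, a SNP segregates according
to the parental genotype pair: `aaxab`, `aaxbc`, `abxaa`, `abxcc` (1:1),
`abxab` (1:2:1) or `abxac` (1:1:1:1). Genotype classes are unphased
letter pairs normalized to alphabetical order, and the female parent is
named first. QC follows a two-stage scheme mirroring common practice for
reduced-representation sequencing:

* per-call (VCF path only): every allele of a heterozygous call needs at
  least 3 supporting reads, a homozygous call at least 5, and the
  genotype quality must reach Phred 30; failing calls become missing.
  Pre-made genotype tables are assumed already call-filtered.
* per-SNP (`filter_snps()`): a SNP is removed when strictly more than 5%
  of the clones are missing (denominator: all clones), or when a plain
  Pearson chi-square test against the Mendelian ratio gives
  $p \le 0.01$ (kept only when $p$ is strictly greater). Both
  boundaries are deliberate readings of "more than 5%" and "$p > 0.01$".
  No continuity correction and no exact-test fallback are applied;
  classes with expected count below 1 are flagged but still tested.

Cross types are inferred from parental calls (`infer_cross_type()`);
offspring-only inference of the segregation type is not implemented, so
either parental calls or an explicit `seg_type` column is required. On
the VCF path, a Mendelian-impossible offspring call (a class outside the
cross's expected set) is set to missing and counted, since a single
per-call genotype is weaker evidence than the inferred cross; in a
declared genotype table the same situation is an error instead, because
the table asserts both the call and the segregation type.

## REML: rotation and optimization

REML estimation of $(V_G, V_E)$ exploits two decorrelations.

1. **Clone-space rotation.** $K = Z'AZ$ has rank $c$: its nonzero
   eigenpairs are obtained from the $c \times c$ matrix
   $N^{1/2} A N^{1/2}$ ($N$ the diagonal matrix of per-clone tree
   counts), while the orthogonal complement — the within-clone contrast
   space — carries pure residual covariance. All likelihood and GLS
   quantities reduce to $c$ rotated columns plus closed-form complement
   totals, costing $O(c^3)$ per rotation instead of $O(n^3)$. This is
   algebraically identical to eigendecomposing the full $n \times n$
   $K$, only cheaper.
2. **Trait whitening.** For a candidate $(V_G, V_E)$, the generalized
   eigendecomposition $L^{-1} V_G L^{-T} = Q \Lambda Q'$ (with
   $V_E = LL'$) turns every rotated observation's covariance into
   $I + d_i \Lambda$, so the multivariate GLS collapses into $m$
   independent weighted least-squares problems. One restricted-likelihood
   evaluation costs $O(m^3 + c\,m\,p^2)$.

The maximizer runs EM-style covariance updates (expectation of the
random-effect outer products conditional on the current GLS fixed-effect
estimates), accepting a step only if the exactly evaluated restricted
likelihood does not decrease, and stops at a relative change below
1e-8 (cap 500 iterations). A BFGS polish on the log-Cholesky
parametrization of both matrices follows; the polished point is accepted
only when it improves the restricted likelihood, so the accepted-iterate
likelihood path is non-decreasing by construction. $V_G$ is clipped to
positive semidefinite and $V_E$'s eigenvalues floored at $10^{-8}$ times
its mean diagonal. The test suite verifies the whole rotated stack —
restricted likelihood, BLUE, Wald F and p — against an independent dense
implementation that literally builds and inverts the $mn \times mn$
covariance on toy problems, and verifies the optimum against random
covariance probes.

**Missing data.** Only trees with a complete $m$-vector of heights enter
the multivariate fit; the complete-case rule is the simplest defensible
choice, and dropped counts are recorded. Per SNP, clones with a missing
call are additionally excluded from that SNP's fit (`n_used` records the
trees actually used).

## The scan

`scan_multivariate()` fits the null model (intercept + blocks) once by
REML. In the default **P3D** mode the null $(\hat V_G, \hat V_E)$ are
reused for every SNP's GLS test — per-SNP REML refits are prohibitively
slow at genome scale, the per-SNP fixed effects barely move the
covariance estimates, and the companion univariate comparison runs under
the same convention. The **exact** mode (per-SNP REML) is retained for
audit; on test panels the two modes agree with Spearman correlation
above 0.99.

Per SNP the scan reports F, degrees of freedom, p, $-\log_{10} p$,
per-time-point effects (for two-class SNPs, the difference between the
two class effects, i.e. twice the contrast coefficient), and

$$R^2 = 1 - \mathrm{RSS}_1/\mathrm{RSS}_0,$$

where both residual sums of squares are $V^{-1}$-weighted quadratic
forms computed under the *null* model's covariance estimate. The source
publication style does not pin down the metric of these RSS; using the
null $\hat V$ for both is this package's documented choice — it keeps
$\mathrm{RSS}_1 \le \mathrm{RSS}_0$ for nested designs, matches the P3D
scan mode, and makes $R^2$ a pure fixed-effect quantity.

Significance uses the Bonferroni threshold $\alpha/n_{\mathrm{tests}}$
(default $\alpha = 0.01$), with the flag inclusive ($p \le$ threshold).
Monomorphic SNPs are reported untestable with $p = 1$ rather than
dropped, so output rows always match input SNPs. Clusters of significant
SNPs closer than 1000 bp are collapsed to their most significant member
(single-linkage chaining, strict `<`, ties to the smaller position), and
`manhattan_table()` lays chromosomes end to end in name order with
scaffolds after.

`two_stage_univariate()` implements the per-time-point comparison scan:
stage 1 extracts clone BLUEs by ordinary least squares on sum-to-zero
block and clone effects; stage 2 scans the BLUEs with the univariate
mixed model ($\sigma^2_g A + \sigma^2_e I$, P3D, one record per clone) —
implemented as the $m = 1$ case of the multivariate scan, so the two
paths cannot drift apart. Clone effects are treated as *fixed* when
extracting BLUEs but as *random* for heritability
($h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$, `heritability()`); the
two readings of the reduced model serve different purposes and are both
provided.

## The synthetic-data generator

`sim_config()`/`simulate_dataset()` generate data with *exactly* the
structure the analysis assumes, so every stage is testable without
external data. Defaults emulate the motivating trial and are fixed
constants of the package:

* 172 clones, 3 blocks, up to 6 cuttings per clone per block, with
  independent Bernoulli survival 1664/3096 ≈ 0.537 per cutting so the
  expected measured-tree count is 1664 (no mortality model beyond the
  resulting count is implied by the design);
* 8 time points with grand means 52–205 cm rising through the season
  (the last increment smallest), CV declining 32% → 22%, and
  heritabilities 0.55 early declining to 0.47 late; the default
  $V_G$/$V_E$ diagonals follow from CV and $h^2$, with
  autoregressive-decay correlations 0.98 (genetic) and 0.95 (residual)
  per time step so adjacent phenotypic correlations exceed 0.94;
* block effects fixed at ±3% of the time-point mean (constants, not
  redrawn per replicate, so stage-1 BLUE tests have known truth);
* a cross-type mixture proportional to the observed segregation
  spectrum (the two 1:1 types dominate), loci simulated without linkage
  — the scan tests SNPs marginally, so LD is not needed for correctness
  testing; a recombination-map mode is future work;
* polygenic values drawn as a component shared by all clones plus an
  independent clone component, each $N(0, 0.5 V_G)$ — exactly
  $\mathrm{Vec}(G) \sim N(0, A \otimes V_G)$ for the full-sib $A$.

Planted QTLs (`make_qtl_spec()`) default to class-effect differences
proportional to the time-point grand mean — on growth traits, locus
effects scale with plant size — with magnitude expressed as a fraction
of the final time point's phenotypic SD. With a declining CV this makes
the standardized effect grow through the season, a trajectory that
deviates from the dominant equicorrelation direction; this is precisely
the regime in which the joint longitudinal test outruns the best
per-time-point univariate scan, as the acceptance suite confirms.

Because heights are physical lengths, the rare simulated tree whose
height vector is not entirely positive (about 1 in 10^3 at the
first-season CV) has its residual redrawn; the stored truth
decomposition still reconstructs every height exactly, which the tests
assert to 1e-10.

What the generator does **not** emulate: spatial autocorrelation within
blocks, block-by-clone interaction, genotyping error, linkage
disequilibrium between markers, and non-Gaussian measurement error.
Passing tests therefore demonstrate correctness of the estimation and
testing machinery under the model's own assumptions, not robustness to
these departures.

## Problem sizes used by the test suite

The suite exercises desk-scale versions of the study conditions, chosen
to make each statistical check well-powered while keeping a full run in
minutes: dense-oracle equivalence on 50 random toys ($n \le 15$,
$m \le 3$); null-scan calibration and type-I error on one 2000-SNP
synthetic dataset (150 clones, 3 blocks, 4 survivors per plot, $m = 3$);
covariance recovery over 25 replicates at the same scale; and the
multivariate-vs-univariate power ordering over 20 replicates with one
planted QTL of half a phenotypic SD.

## Known limitations

* The relationship matrix is the full-sib pedigree form; marker-based
  kinship, dominance and epistatic covariance are out of scope.
* Complete-case handling of partially measured trees discards some
  information; a missing-at-random EM over incomplete height vectors is
  not implemented.
* The Wald test relies on estimated covariance components without
  small-sample df adjustment; with few clones and small $m(n-p)$ the
  test can be mildly liberal.
* Offspring-only segregation-type inference and genotype imputation are
  not provided.
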