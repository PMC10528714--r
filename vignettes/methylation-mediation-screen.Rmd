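---
title: "Screening CpG methylation for mediated causal effects on quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CpG methylation for mediated causal effects on quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epigenome-wide association studies identify CpG sites whose methylation
differs with an exposure such as smoking, but a methylation--trait
association can arise from a causal effect of the CpG on the trait, from
reverse causation (the trait alters methylation), or from confounding —
including *linkage*, where two distinct causal variants in LD drive the CpG
and the trait separately. With only summary statistics (mQTL, eQTL and GWAS
tables) plus a genotype reference panel, this package screens candidate
CpGs for evidence that they *transmit* an exposure's effect to
cardiometabolic-style quantitative traits, and chains the effect through
gene expression when the data support it.

```{r, eval = FALSE}
library(methmr)
study <- simulate_study(scenario_spec(seed = 1))
res <- run_pipeline(study, pipeline_config(seed = 1))
score_results(res, study)
```

## The statistical machinery

**SMR co-localization.** For a probe's top cis-QTL SNP, the Wald ratio
$\hat b_{xy} = \hat b_{GWAS}/\hat b_{QTL}$ estimates the effect of the
molecular trait on the complex trait, and

$$T_{SMR} = \frac{z_{GWAS}^2\, z_{QTL}^2}{z_{GWAS}^2 + z_{QTL}^2}$$

is compared with $\chi^2_1$. $T_{SMR} \le \min(z^2)$ always: the test can
never be more significant than its weaker leg. The ratio's standard error
is the two-sample delta method,
$\mathrm{var}(\hat b_{xy}) = se_G^2/b_Q^2 + b_G^2 se_Q^2/b_Q^4$,
which is also the covariance kernel used everywhere else in the package.

**HEIDI.** Under pleiotropy — a single causal variant affecting both the
probe and the trait — every SNP in LD with the top SNP estimates the *same*
$b_{xy}$; under linkage the estimates disagree. HEIDI selects cis SNPs with
QTL $p <$ `heidi_snp_p` and $r^2$ to the top SNP in
[`heidi_r2_min`, `heidi_r2_max`], computes standardized differences
$z_{d(i)}$ of each SNP's ratio from the top SNP's, and refers
$\sum_i z_{d(i)}^2$ to a weighted sum of $\chi^2_1$ variables with weights
the eigenvalues of the correlation matrix of the $z_d$ (LD-induced). The
tail probability is evaluated by numerical inversion of the characteristic
function (Imhof's method), integrated in oscillation-sized chunks — the
standard infinite-interval quadrature is silently inaccurate on this
integrand — with a Satterthwaite moment match as fallback; the method used
is recorded in the output. Selection constants (defaults
$1.6\times10^{-3}$, $r^2 \in [0.05, 0.9]$, at most 20, at least 3 SNPs) are
configurable; with fewer than 3 qualifying SNPs the test is undefined and,
by default, treated as "cannot reject pleiotropy".

**GSMR-style multi-instrument MR.** Instruments must (1) associate with the
exposure at $p < 5\times10^{-8}$, (2) be in approximate linkage equilibrium
($r^2 < 0.2$, greedy clumping), and (3) survive pleiotropy-outlier removal:
iteratively, SNPs whose ratio deviates from the median ratio with
heterogeneity $p < 0.01$ are removed (skipped below 3 instruments, where a
median is not robust). The surviving ratios are combined by GLS with
covariance $V_{ij} = r_{ij}\sqrt{v_i v_j}$ ($r$ = signed LD from the
panel): $\hat b_{xy} = (1'V^{-1}b)/(1'V^{-1}1)$. With independent
instruments this is exactly inverse-variance weighting; with one instrument
it is the Wald ratio. A ridge of $10^{-6}$ is applied to the correlation
factor when its condition number exceeds $10^8$.

**Pipeline ordering.** Co-localization ($P_{SMR} < 5\times10^{-8}$), then a
HEIDI gate ($p \ge 0.01$), then bidirectional MR: a pair is excluded when
the forward estimate misses $5\times10^{-8}$ or the reverse-direction MR
(trait-associated instruments) is significant at $0.05$. Survivors are
re-estimated with an independent replication mQTL cohort and pass finally
at $p < 5\times10^{-8}$ there too — replication filters on p only, and a
sign-discordant significant replication is flagged rather than dropped.
Mediating genes are then sought among genes whose top eQTL lies within
1 Mb of the CpG: both chain links (CpG→expression, expression→trait) must
reach $5\times10^{-8}$, and the chain's sign product is checked against the
direct estimate. The ordering is enforced and audited: no MR without a
co-localization pass, no replication without discovery, no mediation
without a final pass.

Whether to hard-filter on HEIDI at the screen stage was a genuinely open
choice (one can also merely report it). The gate is on by default because
the screen's purpose is to remove linkage-driven signals before they reach
the MR stage, where a single-locus instrument set cannot distinguish them;
`heidi_gate = FALSE` restores report-only behavior.

**Reverse-direction instruments.** With cis-only molecular QTL coverage,
the reverse MR (trait → CpG) has no usable instruments: the only
trait-significant SNPs with CpG records are the CpG's own cis SNPs, which
are direction-uninformative. The generator therefore emits each probe's
records over its cis window *plus all genome-wide-significant trait SNPs*,
emulating an analyst's lookup of GWAS hits in an mQTL database. A
trait-driven CpG then shows proportional effects at *all* trait loci
(reverse MR significant, pair excluded), while a causal CpG shows nothing
at trait loci off its own locus (reverse MR null or its outlier filter
removes the cis SNPs). A reverse direction with no qualifying instruments
is "not testable" and counts as passing, since the screen filters on
observed reverse significance only.

**Pathway statistic.** For each gene set containing the gene of interest,
eQTLs of member genes at $p < 5\times10^{-8}$ are pooled (a SNP shared by
several member genes keeps its largest $|z|$), pruned to linkage
equilibrium ($r^2 < 0.05$), and the pruned panel's $|z_{eQTL}|$ is
Spearman-correlated with the trait's $|z_{GWAS}|$ at the same SNPs.
Absolute values are used because member genes may act in inhibitory or
activatory directions; $|z|$ is also allele-orientation-free, so no
harmonization is needed at this stage. The p-value is a t approximation for
$n \ge 30$ and an exact-style permutation p (default 10,000 permutations)
below that; at least 10 SNPs are required for a reported result. A
Benjamini--Hochberg q across the tested sets is appended as a clearly
labelled addition to the raw per-set p.

## Allele bookkeeping

Every two-sample comparison first expresses both sides on the same effect
allele: swapped alleles negate $\beta$ and reflect the frequency; strand
flips resolve by complement; palindromic SNPs (A/T, C/G) are aligned by
allele frequency and excluded as ambiguous when either side's MAF exceeds
0.4, the standard two-sample MR compromise — the sources this package
emulates do not state their palindrome policy, so the threshold is
configurable. Signed LD correlations always refer to the panel's counted
alleles, and all records are aligned to the panel before any signed
quantity is combined. The generator deliberately emits ~40% of records
with randomized allele orientation so that the harmonization path is
exercised end-to-end, not just in unit tests.

## What the generator emulates

`scenario_spec()` defines a desk-scale study with known ground truth:

* **LD panel** — 75 blocks × 40 SNPs (3000 SNPs) with exchangeable latent
  correlation 0.9 inside a block (genotype-scale $r^2 \approx 0.6$--0.7),
  Hardy--Weinberg dosages at allele frequencies drawn from [0.05, 0.5],
  500 reference individuals. Blocks sit 0.5 Mb apart, four per chromosome,
  so a CpG's ±1 Mb cis window can span several *independent* signals —
  real cis architectures are multi-signal — while cross-block $r^2$ stays
  at sampling-noise level, which is what keeps clumping from ever merging
  blocks regardless of the window.
* **Cohorts** — discovery mQTL n = 2000 (mirroring an ~2000-subject
  methylation study), replication mQTL n = 1000, eQTL n = 3000 and GWAS
  n = 10,000 (consortium sources scaled to desk size), each an independent
  draw from the same causal model. Summary statistics come from explicit
  per-SNP regressions on simulated individuals, never from a shortcut
  multivariate normal of Z-scores, so LD, allele frequency and
  delta-method behavior stay internally consistent.
* **Topologies** — 5 mediation CpGs (two cis blocks, chain
  CpG→gene→trait with $b_2 = \pm0.7$, $b_3 = \pm0.45$), 5 pleiotropy CpGs
  (three cis blocks; one cis SNP also hits the trait directly, which the
  outlier filter must find), 5 linkage CpGs (one block, two distinct
  causal SNPs), 5 reverse CpGs (no cis effects of their own; methylation
  = 0.9 × trait + noise, probe located at a trait locus), 80 null CpGs
  sharing 12 blocks. Three traits additionally carry their own loci and
  trait-affecting "support" genes; 12 decoy genes have eQTLs but no trait
  effect.
* **Pathways** — per trait, a causal set (mediator + support genes, ≥10
  independent significant eQTL SNPs after pruning), one decoy set, and
  mixed filler sets. All trait-affecting genes share the same effect
  magnitude (0.45, signs vary): a uniform proportionality between
  $|z_{eQTL}|$ and $|z_{GWAS}|$ across member genes is exactly what the
  rank correlation detects, and mixing magnitudes would test a different
  (and weaker) hypothesis than the pathway model poses.
* **Exposure** — a binary smoking variable (prevalence 0.25) shifts every
  candidate CpG by ±[0.1, 0.3]; it exists so the EWAS-style candidate
  table has realistic effect/direction columns and plays no role in the
  genetic analyses.

Effect sizes were fixed once by a power calculation at these sample sizes
(e.g. a mediation CpG's top cis SNP reaches GWAS $z \approx 8$--10 on its
trait), so the planted topologies are recoverable but not trivially so;
they are conditions of the validation study, not tuning knobs.

What the generator does **not** emulate: realistic human LD maps (blocks
are exchangeable, not decaying), binary disease traits (everything is a
quantitative liability), trans-QTLs beyond the trait-hit lookup, sample
overlap between cohorts, population stratification, or winner's-curse
selection into the candidate list. Passing tests therefore demonstrate
that the statistics and the screening logic are correct and calibrated
under the stated model — not that real consortium data would yield the
same operating characteristics.

## Numerical choices and degenerate inputs

* p-values are floored at $10^{-300}$ rather than underflowing to 0.
* Clumping ties (equal p) break by ascending position then SNP id, so runs
  are reproducible; the clump window defaults to 10 Mb for instrument
  selection and 250 kb for pathway pruning (the screening rules state only
  the $r^2$ thresholds, so the windows are implementation defaults).
* Monomorphic SNPs are flagged in the panel (r² undefined) and skipped by
  scans; missing dosages use pairwise-complete correlation, never
  imputation.
* A zero QTL effect at the top SNP is an explicit undefined-ratio error;
  a zero-residual regression keeps se = 0 with the p floor.
* Eigenvalue mixtures clip tiny negative eigenvalues; a non-PSD $z_d$
  correlation matrix gets a minimal ridge with a warning.
* All randomness flows from a single seed per study (generator) and per
  pipeline run (permutations), making exported tables byte-identical
  across reruns.

## Problem sizes used in the test suite

The packaged validation runs at the generator's default sizes: 500/2000/
1000/3000/10,000 individuals (panel/discovery/replication/eQTL/GWAS),
single-locus HEIDI scenarios at 3000 QTL / 8000 GWAS individuals with 500
replicates, 500 GSMR recovery replicates at n = 20,000 per cohort, 20
full-pipeline seeds, and 200 pathway replicates. These sizes give stable
acceptance statistics on a single CPU while keeping each property's
Monte-Carlo error well inside its asserted margin.

## Known limitations

* The reverse-causation screen inherits the coverage limits of cis-only
  QTL resources; the trait-hit lookup is a model of practice, not a
  guarantee that real mQTL databases contain those SNPs.
* HEIDI is mildly conservative here (delta-method variances and an
  estimated LD matrix), which costs a little power against linkage at
  marginal sample sizes.
* GSMR's published iterative weighting is not reproduced verbatim; the
  GLS form with median-based outlier detection is documented and validated
  against its own oracles (IVW equality, coverage, planted-outlier
  recovery).
* Single-instrument pairs cannot be outlier-filtered; a genuinely
  pleiotropic single-SNP architecture is indistinguishable from causality
  by this design, as it is for any summary-statistics method.
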