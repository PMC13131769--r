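---
title: "Four-tier causal prioritization of cell-type cis-eQTLs: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-tier causal prioritization of cell-type cis-eQTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome-wide association studies localize disease risk to loci, not genes:
a typical locus holds dozens of variants in linkage disequilibrium (LD) and
many genes, and the causal chain variant → expression → disease is invisible
to the association statistic alone. `snqtl` implements a pipeline that
resolves this at cellular resolution for brain disorders with strong
neuropathological context (the motivating case is Parkinson's disease):
single-nucleus RNA-seq of post-mortem tissue is pseudobulked per cell type,
cis-eQTLs are mapped per dataset and combined by meta-analysis, and each
significant gene × cell type then has to survive four statistical tiers
before it is called a candidate causal risk gene:

1. **cis-eQTL significance** — the RE2 meta-analysis p-value of some cis
   variant is at or below a Bonferroni threshold computed over the realized
   number of unique eSNP–eGene pairs;
2. **colocalization** — a Bayesian posterior probability of at least 0.8
   that the expression signal and the GWAS signal in an LD chunk share a
   single causal variant (PP4);
3. **Mendelian randomization** — the summary-based MR test links expression
   to disease risk below a Bonferroni threshold over the forwarded eGenes;
4. **no linkage** — the HEIDI heterogeneity test fails to reject the
   single-shared-variant model (p ≥ 0.01).

Orthogonal evidence layers — single-nucleus allelic imbalance, replication
in bulk cohorts, and pathology-score-dependent (dynamic) eQTLs — annotate
but never gate the prioritized set.

Because the human data such a study rests on are access-restricted, the
package ships a synthetic-cohort generator with planted ground truth, and
every stage is validated against it: null calibration, closed-form oracle
equivalence, parameter recovery, and end-to-end prioritization of planted
shared-causal genes with rejection of planted linkage decoys.

# Stage models and assumptions

## Pseudobulk expression

Per cell, each gene's UMI count is divided by the cell's total and
multiplied by 10,000 (counts per 10k); per subject and cell type the
pseudobulk value is the mean over that subject's cells. Subjects with fewer
than `min_cells` (default 10) cells of a type are treated as missing for
that type rather than averaged over a handful of noisy cells. The default
floor is a compromise: high enough that a pseudobulk mean is a stable
subject-level quantity, low enough that rarer cell types retain most
subjects.

Adjustment proceeds in two stages. Batch structure is removed per gene
either by matching each batch's location/scale to the pooled moments
(`meanvar`, the default, exactly removes a planted constant shift) or by a
parametric empirical-Bayes model that shrinks per-batch locations and
scales toward their across-gene means before adjustment (`eb`). The EB
variant deliberately leaves a shrinkage residual of the order of the
location-noise SD — that is the bias/variance trade the prior buys — so
exactness tests apply to `meanvar` and proportional-removal tests to `eb`.

Hidden structure is then absorbed by surrogate factors: each gene is
regressed on the known covariates (age, sex, RIN, PMI), and the top
`n_hidden` principal components of the **gene-standardized** residual
matrix join the design before final residualization. Standardizing genes
before the PCA is a deliberate departure from covariance-scale PCA: with a
compact gene panel, one high-expression gene can dominate the leading
covariance eigenvector, and if that gene carries a genuine cis effect the
"surrogate" silently regresses the signal away (we observed realized
effects crushed by more than half on some simulation seeds). On the
correlation scale a single-gene direction is bounded by one unit of
variance and stays below the noise eigenvalues, while genuinely shared
structure (batch, library quality) still surfaces first. The default of 30
factors mirrors common practice on transcriptome-wide panels; the pipeline
driver uses 2 because the synthetic panel has only ~16 genes and more
surrogates would not be identifiable. The cap `subjects − rank(known) − 1`
is enforced with a warning.

Z-scaling ((x − mean)/SD, sample SD) puts every gene on the same scale, so
downstream eQTL effects read as SDs of expression per effect allele.

## cis-eQTL regression

For each gene, every candidate variant within 1 Mb of the gene body
(positions 1-based, window inclusive on both ends: a variant at exactly
start − 1,000,000 is cis) is tested by ordinary least squares of z-scaled
expression on allelic dosage. Covariates were already residualized out, so
the model is the simple regression with a two-sided t test at n − 2 df.
Missing dosages are excluded pairwise, never imputed; pairs with fewer than
20 complete subjects or zero dosage variance are skipped — 20 is the floor
below which a t test on a 3-level regressor stops being meaningful. The
dynamic-eQTL model adds the pathology score: expression ~ dosage + score +
dosage·score, reporting the interaction coefficient; variables enter raw by
default (a `center` flag exists because the interaction coefficient's main
effects are only interpretable at centered variables, but the test of the
interaction itself is identical either way).

## Meta-analysis

Per (gene, variant, cell type) triple across datasets: fixed-effects
inverse-variance pooling; DerSimonian–Laird random effects (the
"conservative" effect-size source — its SE never undercuts FE); and the
Han–Eskin RE2 likelihood-ratio test of β = 0, τ² = 0 against
b_i ~ N(β, se_i² + τ²), with τ² profiled by golden-section search on
[0, 100·max(se²)] and the boundary value τ² = 0 always compared in.
Downstream stages use the RE2 p-value for significance and the RE effect
and SE as the effect estimate — the RE2 statistic has no natural effect
size, and RE is the conservative choice.

The RE2 null is the half-half χ²₁/χ²₂ boundary mixture. We use this
closed-form asymptotic rather than tabulated small-k corrections, and the
choice has a measurable cost: at k = 4 studies the empirical type-I error
at α = 0.05 is ≈ 0.031 (20,000-replicate Monte Carlo), i.e. the test is
*conservative* at small k (the tabulated corrections exist precisely to
recover this lost power). The acceptance suite pins the empirical rate and
documents the deviation rather than hiding it; at the pipeline's Bonferroni
thresholds the conservatism only strengthens family-wise control.

A related property worth knowing: under a homogeneous alternative with
τ̂² = 0 the RE2 statistic equals z_FE² but pays the mixture tail, so its
p-value is strictly above the FE/RE p there; RE2 undercuts RE mostly once
real heterogeneity appears. Its detection rate stays within a few points of
FE under homogeneity — that is the design trade.

## LD chunks

Greedy clumping mirrors the classic PLINK semantics: repeatedly take the
unassigned variant with smallest p ≤ p1 as a lead and absorb unassigned
variants with p ≤ p2, r² ≥ 0.1 with the lead, within 500 kb lead-to-member.
Ties on p break by position then identifier so the output is invariant to
input order. eQTL chunks use the eQTL Bonferroni threshold as p1 = p2;
GWAS chunks use 5 × 10⁻⁸. Records from different cell types whose eSNPs
land in one chunk count as the same eQTL signal; per chunk and cell type a
detection flag records whether any member passed the threshold there.
Cross-cell-type sharing is quantified by the fixed-λ Storey estimator
π₁ = 1 − min(1, #{p > λ}/(m(1 − λ))) at λ = 0.5; the spline-smoothed
variant buys little at these test counts.

Conditional (secondary-signal) chunking beyond the greedy clump is not
implemented; the chunk table is the hook where a stepwise conditional
analysis would attach.

## Colocalization

Wakefield log approximate Bayes factors, lABF = ½log(1−r) + ½rz² with
r = W/(V+W), with prior effect SDs W^½ = 0.15 for the quantitative
expression trait and 0.2 for the case-control trait on the log-odds scale
(the standard defaults of the ABF literature); hypothesis priors
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵. The five posteriors follow the standard
log-space sums under the single-causal-variant assumption; the H3 term
e^{L1+L2} − e^{L12} is computed by log-diff-exp and clipped at zero. When a
trait lacks betas, V is reconstructed as 1/(2·N·maf·(1−maf)) from p, MAF
and N.

Pairing matters more than the arithmetic: each significant gene × cell
type is tested against every GWAS chunk overlapping its cis window, and
the SNP set is the cis window intersected with the chunk span **padded by
the clumping distance window** (500 kb). The padding is load-bearing: a
chunk whose only genome-wide-significant member is its lead has a
zero-width span, and a single-SNP "colocalization" cannot represent H3 at
all — PP4 inflates toward 1 and a linkage signal masquerades as shared. In
our linkage simulations the padded region restores the neighbourhood and
the decoys fall to PP3, which is also how colocalization regions are formed
in practice.

## SMR and HEIDI

With the top eSNP (smallest RE2 p among instruments with |z_eQTL| ≥ 3) as
instrument, b_xy = b_GWAS/b_eQTL estimates the trait effect per SD of
expression, tested by T = z_g²z_e²/(z_g²+z_e²) on χ²₁. HEIDI asks whether
b_xy estimated from LD neighbours (eQTL p < 1.57 × 10⁻³, r² to the top
eSNP in [0.05, 0.9], pruned at pairwise r² ≤ 0.9, at most 20, at least 3)
deviates from the top-SNP estimate: the d_i = b_xy(i) − b_xy(top) get a
delta-method covariance in which summary statistics correlate with LD r,
and S = Σz_{d_i}² is referred to a Satterthwaite-matched scaled χ² from
the eigenvalues of the z_d correlation matrix. Fewer than 3 usable
neighbours means no HEIDI result; such genes are excluded from tier 4 by
default (`heidi_missing = "pass"` exists, but a gene whose linkage status
cannot be assessed should not silently pass a linkage test). The multi-SNP
SMR statistic sums T over the selected set and uses the eigenvalues of the
signed LD correlation matrix for its Satterthwaite reference — signed,
because Var(Σz²) = 2Σr_ij² = 2Σλ(R)², which the squared matrix's
eigenvalues do not reproduce; the null simulation (type-I ≈ 0.046 at 0.05)
confirms the choice.

## Allelic imbalance

Phased UMI counts are summed to (subject, cell type, variant); only
heterozygous subjects are informative and only variants with at least 20
summed phased UMIs are tested (inclusive boundary). The test is a
beta-binomial ML fit in the (μ, φ) parameterization with a logit-link mean
and free overdispersion, against the null μ = 0.5 with φ still free — the
mean is the hypothesis, overdispersion is a nuisance — via a χ²₁ LRT. Note
a consequence of keeping φ free: totally imbalanced input (every subject
100% one allele) is partially explained by a (μ = 0.5, φ → 1) mixture, so
the attainable LRT is capped near 2·n·log 2 and the p bottoms out around
10⁻⁷ for 20 subjects rather than vanishing; μ̂ is then clipped to
[10⁻⁶, 1−10⁻⁶] and flagged.

Numerics: optimization runs on (logit μ, log-odds φ) with Nelder–Mead from
μ starts {0.3, 0.5, 0.7} and φ starts {0.01, 0.1}, restarted once at the
optimum; the null profile is a golden-section search. Below φ = 10⁻⁶ the
lbeta formulation loses precision (its shape parameters grow like 1/φ), so
the binomial limit takes over there, and the exact φ = 0 binomial candidate
is always compared in — without it the optimizer can "improve" on the
boundary by floating-point noise.

Concordance couples the ASE log-odds (aligned to the effect allele) to the
eQTL meta effect by Pearson correlation over matched (gene, variant, cell
type) triples.

# The synthetic cohort

The generator emulates the study conditions end-to-end; its defaults are
the conditions under which all recovery claims are made.

* **Cohort**: 3 datasets × 400 subjects, nine cell types (dopaminergic and
  cortical neuron classes, glia, vascular), 20 nuclei per subject and type
  — deliberately at the low end of per-type nucleus counts so pseudobulk
  noise is realistic for rarer types.
* **Genotypes**: two haplotypes per subject from thresholding an AR(1)
  Gaussian process at MAF-matched quantiles, eight loci of 25 variants
  (4 kb spacing) on separate chromosomes. The latent step correlation is
  *calibrated* (via the bivariate-normal orthant probability) so the
  realized binary haplotype correlation matches `ld_decay` (default 0.8):
  thresholding attenuates latent correlation substantially, and an
  uncalibrated chain with latent 0.9 realizes only r ≈ 0.4–0.7 depending
  on MAF. MAF is drawn per locus (0.15–0.45) with ±0.01 per-variant
  jitter, since strong LD forces near-identical frequencies; this also
  keeps the calibration within the Fréchet bound the margins impose.
* **Expression**: negative-binomial UMI counts (size 2) with log-normal
  library factors (sdlog 0.3), per-batch log-mean shifts (SD 0.15, two
  batches), and planted cis effects of 0.5 on the log-mean scale in four
  of the nine cell types. Gene baselines are drawn once per cohort and
  shared by all datasets — expression level is a biological property, and
  redrawing it per dataset manufactures cross-dataset heterogeneity
  (attenuation differences drove Cochran's Q into the tens before this
  choice). The planted 0.5 log-scale effect realizes roughly 0.3–0.5 SD
  per allele after pseudobulking and z-scaling, comfortably detectable at
  these sample sizes.
* **GWAS**: summary statistics simulated directly in z-space, z ~
  N(Rz*, R) with R the realized dosage correlation of the locus and the
  causal z* = 8 at an effective N of 50,000; β and SE follow from the
  unit-variance-trait scaling 1/sqrt(2f(1−f)N). Half the loci share the
  expression causal variant, a quarter plant the trait causal at realized
  r² ≈ 0.25 to it (the linkage decoys), a quarter are null.
* **ASE**: for heterozygous subjects at tested variants, beta-binomial
  counts with logit(μ) = κ·effect (κ = 1 by default — the coupling is
  reported as concordant in the motivating literature but no mapping is
  published, so the slope is configurable) and overdispersion 0.05 at ~40
  phased UMIs per subject.

What the generator does **not** emulate: realistic cell-type proportions,
doublets, ambient RNA, reference-mapping bias in the allele counts,
population structure, or genotype uncertainty. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
its stated models — not that those models absorb every artifact of real
tissue data. One emulated artifact deserves mention: because counts are
normalized per cell total, a strong planted effect on one gene induces a
small opposite-sign compositional effect on same-locus genes; with a small
gene panel this is visible and occasionally promotes a passenger gene at a
truly shared locus, which is faithful to how per-cell normalization behaves
(and to the pleiotropy the four-tier design deliberately preserves — all
cis-regulated genes of a chunk are reported, never collapsed to one).

# Problem sizes used in validation

The test-suite and acceptance-script sizes are chosen so each claim has
enough replicates to be sharp while the whole validation stays desk-scale:
5,000 null regressions / RE2 replicates, 2,000 interaction pairs, 1,000
beta-binomial cohorts, 500 HEIDI / multi-SNP-SMR replicates, 100
colocalization replicates per scenario, 200-replicate parameter recovery,
20 all-null pipeline seeds, and 6 planted-cohort seeds (24 shared-causal
gene chances, 12 linkage decoys). The bulk-replication layer runs two
cohorts of 150 subjects. Thresholds and tolerances in the tests come from
the statistics themselves (3 binomial SEs of the nominal rate; stated
closed-form values to printed precision), never from observed outcomes.

# Known limitations

* RE2 small-k conservatism (above) — power, not validity, is affected.
* DerSimonian–Laird is the RE flavour; likelihood-based τ² estimates
  differ at small k and no attempt is made to match any specific software's
  RE beyond the stated formulas.
* The multi-SNP SMR test is a Satterthwaite approximation to the weighted
  χ² sum, validated by calibration rather than by matching a reference
  implementation's values.
* Single-causal-variant colocalization only; multi-signal loci are paired
  chunk-by-chunk, all overlapping pairs emitted.
* Multi-allelic sites are rejected at parse time; strand-ambiguous
  palindromic variants with allele frequency in [0.4, 0.6] are dropped at
  harmonization (both windows configurable).
* The beta-binomial GLM is intercept-only (no covariates), matching the
  pseudobulk ASE design; reference-bias correction is assumed upstream.
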