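# snqtl — four-tier causal prioritization of cell-type cis-eQTLs at GWAS loci

GWAS loci implicate regions, not genes: each association peak spans dozens
of variants in linkage disequilibrium and often several genes, and the
mechanism — which variant regulates which gene in which cell type, and
whether that regulation drives disease risk — is left open. `snqtl` is an R
implementation of a prioritization pipeline for exactly this gap, built for
single-nucleus RNA-seq of post-mortem brain tissue (the motivating disease
is Parkinson's) and validated end-to-end on synthetic cohorts with planted
ground truth. It is aimed at statistical geneticists and computational
biologists who want the whole chain — pseudobulk eQTL mapping through
Mendelian randomization — as tested, composable functions rather than a
stack of heterogeneous command-line tools.

## The statistical core

For subject-level pseudobulk expression $y$ (counts-per-10k, covariate- and
surrogate-adjusted, z-scaled) and allelic dosage $x$, per dataset and cell
type the cis model is the additive regression $y = \beta x + \varepsilon$
over all variants within 1 Mb of the gene. Across datasets each
(gene, variant, cell type) triple is combined three ways: fixed-effects
inverse variance; DerSimonian–Laird random effects; and the Han–Eskin RE2
likelihood-ratio statistic

$$S = -2\left[\ell(\beta{=}0,\tau^2{=}0) - \max_{\beta,\tau^2\ge0}
\ell(\beta,\tau^2)\right],\qquad
p = \tfrac12 P(\chi^2_1 \ge S) + \tfrac12 P(\chi^2_2 \ge S),$$

under $b_i \sim N(\beta, se_i^2+\tau^2)$. A gene × cell type is
**prioritized** when it passes all four tiers:

| tier | statistic | pass rule |
|---|---|---|
| 1 | RE2 meta p | $\le \alpha/m$ over the realized unique eSNP–eGene pairs |
| 2 | colocalization PP4 (Wakefield ABFs, priors $10^{-4},10^{-4},10^{-5}$) | $\ge 0.8$ for an overlapping GWAS LD chunk |
| 3 | SMR $T = z_g^2 z_e^2/(z_g^2+z_e^2)$ (single- or multi-SNP) | $p \le \alpha/\,$#forwarded eGenes |
| 4 | HEIDI heterogeneity | $p \ge 0.01$ (no evidence of linkage) |

Supporting layers — beta-binomial allelic imbalance on phased UMIs
(≥ 20 per variant), replication in bulk cohorts at BH-FDR ≤ 0.05, and
genotype × pathology-score interactions at nominal p ≤ 0.01 — annotate the
prioritized genes. LD clumping (greedy, r² ≥ 0.1 within 500 kb), the π₁
sharing statistic, allele harmonization, and readers/writers for VCF,
Matrix-Market counts, and GCTA-dialect summary statistics round out the
toolkit. The synthetic-cohort generator (`simulate_cohort()`) plants
cell-type-specific cis effects, shared-causal / linked-causal / null GWAS
architectures consistent with the genotype LD, and coupled allelic
imbalance, and returns the ground truth alongside the data.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort
(3 datasets × 200 subjects, nine cell types, eight loci — four with a
shared causal variant, two with a linked decoy variant at r² ≈ 0.25, two
null):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pseudobulk_eqtl.R
Rscript analysis/03_meta_chunks.R
Rscript analysis/04_coloc_smr.R
Rscript analysis/05_ase_dynamic_bulk.R
Rscript analysis/06_prioritize.R
```

which prints, stage by stage:

```
Bonferroni threshold over 400 pairs: 0.000125
565 significant records, 7 eGenes, 4 cell types
12 independent eQTL chunks (7 primary + 5 additional)
pi1 of GLU eSNPs in other cell types: 0.28 (1152 tests)
6 independent GWAS chunks
coloc: 25 gene-chunk pairs, 13 with PP4 >= 0.8
SMR: 24 tests, 24 below the 0.00714 threshold, 16 passing HEIDI (p >= 0.01)
snASE: 144 tests, 32 significant at 0.05; eQTL concordance r = 0.91 (p = 1.1e-55, n = 144)
dynamic eQTLs: 1341 interaction tests, 14 at nominal p <= 0.01
bulk replication: 400 records, 7 genes at FDR <= 0.05
Prioritized genes: gene_L1_1, gene_L2_1, gene_L3_1, gene_L4_1
Shared-causal recovery: 4 / 4; linkage-locus genes prioritized: 0
Evidence among prioritized: ASE 4, bulk 4, dynamic 3
```

Reading this: of 400 tested eSNP–eGene pairs, 7 genes reach tier 1 and
split into 12 independent LD-chunk signals; colocalization and SMR/HEIDI
then discard the two linkage decoys and the compositional passengers,
leaving exactly the four genes whose shared causal variant was planted —
each supported by allelic imbalance and bulk replication. The π₁ of 0.28
says about a quarter of the glutamatergic-neuron signals are detectably
shared with other cell types, reflecting that effects were planted in four
of nine types. The tier thresholds (1.25 × 10⁻⁴, 7.14 × 10⁻³) are computed
from the realized test counts, not fixed constants.

The same machinery as a single call:

```r
library(snqtl)
res <- run_pipeline(sim_config(seed = 1))
res$report          # Table-1-style risk-gene table
res$manifest        # thresholds and per-stage row counts
```

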