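# meqtlmap

Mapping methylation quantitative trait loci (meQTLs) in population samples:
a desk-scale, fully tested R implementation of the analysis pipeline used in
population epigenomics studies that profile CpG methylation on arrays
(two technical replicates per individual), genotype the same individuals at
dense SNP panels, and measure gene expression by RNA-sequencing.

It is aimed at statistical geneticists and epigenomics analysts who want
each stage of such an analysis as a composable, testable function — from raw
replicate intensities to cis/trans meQTLs with permutation-calibrated FDR,
annotation enrichment, and methylation–expression integration — plus a
synthetic-data generator that reproduces the statistical structure of the
real data so the whole pipeline can be exercised and validated without any
external downloads.

## What it computes

**Phenotype construction.** Methylation at each CpG probe is the beta value
β = M/(M+U), the fraction of methylated-bead signal. Replicate arrays are
quantile-normalized onto their common mean order statistics, averaged, then
each probe is transformed to N(0,1) by the rank-based inverse-normal
transform Φ⁻¹((r − ½)/n). The first k (default 3) principal components of
the normalized individual × probe matrix are regressed out to absorb batch
and other hidden confounders.

**Association.** For probe j and SNP s the single-locus additive model

  y_ij = μ + b g_is + ε_ij

is fit by least squares, where g is the minor-allele dosage in [0, 2]; the
slope b is the phenotype change per allele copy, tested with a two-sided t
test on n − 2 df, and r² is the variance explained. The cis scan tests all
SNPs within 50 kb of the probe; the trans scan tests genome-wide and labels
each probe's best hit cis/trans by the same 50 kb rule.

**FDR.** Significance is calibrated by permuting individual labels of the
whole phenotype matrix (preserving co-methylation), rerunning the scan, and
taking the best signal per probe per replicate (10 replicates for cis, 1
for trans). FDR(t) is the mean permuted count of probes with best p ≤ t over
the observed count, and the reported threshold is the largest t with
FDR(t) ≤ 10%.

**Enrichment.** A Bayesian hierarchical model asks where meQTLs sit: each
probe harbors at most one causal SNP (shared prior probability p₁); given
one, the prior that it is SNP i is softmax(Σ_k λ_k a_ik) over the probe's
cis SNPs, with a covering distance bins around the probe and binary
annotations (TF-binding sites, histone marks). Per-SNP evidence enters as
Wakefield approximate Bayes factors; (λ, p₁) are estimated by EM with
observed-information confidence intervals.

**Integration.** Promoter methylation (nearest probe within 2 kb of the
TSS) is correlated with expression within and across individuals, with a
10,000-permutation tail-enrichment test; meQTL SNPs are tested as eQTLs
against MAF- and distance-matched control SNP sets; and the eQTL scan is
re-run on methylation-residual expression to count mediated associations.

## Worked example

```r
library(meqtlmap)

cfg <- sim_config(n_individuals = 77, n_probes = 300, probes_per_gene = 3,
                  fraction_probes_with_meqtl = 0.2, effect_fixed = 1, seed = 1)
study <- simulate_study(cfg)

mset <- preprocess_methylation(study$methylation$replicates, k = 3)
classify_states(mset$beta)
#> methylation states over 300 probes: 70.0% unmethylated, 16.7% hemi, 13.3% methylated

fdr <- permutation_fdr(mset$residual, study$genotypes,
                       study$methylation$probes, scan = "cis", seed = 1)
fdr
#> permutation FDR (cis, 10 replicates): 65 discoveries at target FDR 0.1 (p <= 0.00126)

head(fdr$discoveries[, c("probe_id", "snp_id", "distance", "slope", "p", "r2")], 3)
#>             probe_id     snp_id distance      slope            p        r2
#> snp0001_051  cg00002 snp0001_05   -28095 -0.8240095 9.232891e-08 0.3180797
#> snp0002_132  cg00006 snp0002_13    24550 -1.0058390 7.483362e-07 0.2800760
#> snp0006_10   cg00016 snp0006_10     5947 -0.8370032 1.298408e-07 0.3120152
```

The state fractions recover the generator's trimodal baseline mixture; the
65 discovered probes are those whose best cis p-value clears the
permutation-selected threshold, and each row reports the SNP, its signed
distance to the probe, the per-allele effect on the PC-corrected normalized
phenotype, and the variance explained. Checking the discovery list against
the generator's truth table here gives a realized false-discovery
proportion of 0.138, consistent with the 10% target given Monte-Carlo noise
at one seed.

`run_pipeline(default_run_config())` chains all stages (simulate → QC →
preprocess → describe → scan → FDR → integration) from a single config —
also loadable from YAML via `read_run_config()` — and writes result tables
plus a manifest to the output directory.

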