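---
title: "Methods: the meqtlmap methylation-QTL pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the meqtlmap methylation-QTL pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meqtlmap)
```

# Scope and model

meqtlmap maps methylation quantitative trait loci (meQTLs) from array beta
values and SNP dosages in a population sample, and relates them to gene
expression. This vignette documents the statistical choices in enough
detail that a reader can audit or reimplement every stage.

## Phenotype construction

Methylation at a CpG probe is summarized as the beta value
$\beta = M/(M+U)$, the methylated fraction of total bead signal, in
$[0, 1]$. A probe/sample pair with $M + U = 0$ is missing.

Technical replicate arrays are **quantile-normalized jointly**: every
(individual, replicate) array is mapped onto the mean of the order
statistics across all arrays, preserving within-array ranks; tied values
within an array receive the mean of their target quantiles (via
`limma::normalizeQuantiles(ties = TRUE)`). Joint normalization — rather
than pairwise within each individual — also equalizes individual-level
distributions, which the downstream association model implicitly assumes;
the alternative reading (normalizing each individual's pair separately)
would leave individual-level scale differences for the rank-normal step to
absorb and gives nearly identical results on rank-based statistics.

Replicates are then averaged per (individual, probe), ignoring missing
entries. Each probe is transformed to a standard-normal phenotype by the
rank-based inverse-normal transform $\Phi^{-1}((r - 0.5)/n)$ with average
ranks for ties. The offset $(r - 0.5)/n$ is the symmetric convention; the
alternative $r/(n+1)$ differs negligibly at the sample sizes involved.

Finally, hidden structure is removed by **principal-component correction**:
PCs are computed on the individual × probe matrix (individuals as
observations, probe-wise centering; no re-scaling, since the rank-normal
columns already have unit variance, making the covariance and correlation
orientations equivalent), and each probe column is replaced by its
least-squares residual on the first $k$ PC score vectors. The default
$k = 3$ targets batch-like confounders (e.g. sample-processing phase) that
load on the leading PCs; `k = 0` disables the correction and returns the
input unchanged. Missing values are mean-imputed per probe for the PCA and
restored afterwards.

## Association and FDR

Association uses the single-locus additive model: ordinary least squares of
the phenotype on minor-allele dosage with intercept, a two-sided $t$ test
on $n - 2$ df, and $r^2$ equal to the squared sample correlation. The cis
scan tests every SNP within 50 kb of the probe (inclusive window, same
chromosome); best-per-probe ties are broken by smaller |distance|, then
lexicographic SNP id, for determinism. Monomorphic SNPs in the analyzed
subset are skipped with a recorded reason. Missing hard-call dosages are
mean-filled per SNP at load time — a light-weight stand-in for
posterior-mean imputed genotypes — and monomorphic SNPs are dropped.

The **permutation FDR** permutes individual labels of the entire phenotype
matrix jointly, so inter-probe correlation (co-methylation) survives into
the null and the best-per-probe order statistics are taken over the same
dependence structure as the observed data; a per-probe independent
permutation mode exists for comparison but is not the default. Each of the
`n_reps` replicates (10 for cis, 1 for trans, matching standard practice
for these scan sizes) records the best p per probe. The estimate is
$\widehat{FDR}(t) = \bar{V}(t) / R(t)$ — the mean permuted count of probes
with best $p \le t$ over the observed count — evaluated on the exact step
function of sorted observed best-p values (no arbitrary grid), and the
selected threshold is the largest $t$ with $\widehat{FDR}(t) \le$ target
(default 10%). If no threshold qualifies, the discovery set is empty but
the table is still returned. When scoring calibration against simulation
truth we use the standard $FDP = V/\max(R, 1)$ convention. Sex is not a
covariate in the main scans (the PC correction is the only adjustment); a
separate interaction scan fits
`phenotype ~ dosage + sex + dosage:sex` and reports the interaction-term p.

Because all 500 (or 21k) probes — causal ones included — are permuted, the
numerator estimates the null count over *all* probes while false
discoveries can only come from the null subset; the estimator is therefore
conservative by roughly a factor $1/\pi_0$, partly offset by the variance
of the ratio at the selected threshold. Its realized calibration is what
the acceptance checks measure empirically.

## Hierarchical enrichment model

Evidence per (probe, SNP) pair enters as the Wakefield asymptotic Bayes
factor
$ABF = \sqrt{se^2/(se^2+W)}\,\exp\!\big(z^2 W / (2(se^2+W))\big)$,
with prior effect variance $W = 0.15^2$ by default on the
standardized-phenotype scale; this is the standard asymptotic form for
summary statistics and is validated in the tests against direct quadrature
of the normal–normal marginal ratio. The enrichment model assumes at most
one causal SNP per probe, a shared prior probability $p_1$ that a probe has
any meQTL, and a conditional-logit prior over the probe's cis SNPs,
$\pi_{ij} \propto \exp(\sum_k \lambda_k a_{ijk})$, with the design covering
|distance| bins (default edges 0, 1, 2.5, 5, 10, 25, 50 kb, nearest bin as
reference — the region immediately surrounding the probe is where cis
effects concentrate) plus binary annotation indicators. $(\lambda, p_1)$
are estimated by EM — the M-step for $\lambda$ is a probe-weighted
conditional-logit fit by BFGS — with the log-likelihood asserted
non-decreasing at every iteration; 95% CIs come from the observed
information at the optimum (with $p_1$ on the logit scale). One-causal-per-
probe keeps the likelihood tractable and matches the intended use:
estimating *where* effects sit, not fine-mapping multiple signals.

The observed-information CI is asymptotic in the number of informative
probes and is only trustworthy when the causal SNP is reasonably well
identified within its window. The recovery checks therefore use 200 probes
of 20 cis SNPs with causal z-scores centered at 5: at that signal strength
the empirical coverage of the 95% CI is nominal, whereas with weaker,
ambiguous signals (causal z near 4) the finite-sample upward bias of the
softmax MLE erodes coverage to roughly 90% — a known small-sample property
of such models, not an implementation defect, and worth remembering when
interpreting real-data fits with weak signals.

## Methylation–expression integration

Genes are paired with their promoter probe — the probe nearest the TSS
among those within 2 kb (ties: smaller |distance|, then probe id). Within-
individual correlation is the Spearman correlation across genes between
promoter beta and expression, per individual. Cross-individual correlation
is per-gene Spearman across individuals; its permutation test jointly
permutes the individual labels of expression (preserving inter-gene
correlation), and counts genes beyond the *observed* distribution's own
25% and 5% quantiles in both tails — cutoffs are frozen from the observed
data and the permuted statistic is the count beyond them, the reading that
makes the test well-defined; each tail's empirical p is
$(1 + \#\{perm \ge obs\})/(n_{perm}+1)$.

Matched control SNP sets bin the case SNPs jointly on MAF (case-set
deciles) and |distance| (equal case-count bins, default 5), with open
outer bins so pool SNPs slightly outside the case range join the extreme
bins, and draw each control set with identical per-cell counts (without
replacement within a set; under-filled cells are sampled with replacement
and flagged, empty cells are an error).

The residual-eQTL re-analysis runs the cis-eQTL pipeline (rank-normalized
expression, 50 kb window around the TSS, permutation FDR) twice: on the
original expression and on per-gene residuals after least-squares
regression on promoter beta, re-rank-normalized. Genes with constant
promoter beta are left unadjusted and flagged. Each pipeline selects its
own threshold at the common FDR target, and the report counts shared,
original-only and residual-only discoveries — original-only genes are the
mediation candidates.

# The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its truth tables. Per probe $j$ and individual $i$ the
latent logit-methylation is

$$m_{ij} = \mu_j + b_j g_{i,s(j)} + \textstyle\sum_k w_{jk} u_{ik}
  + s_j\,\mathrm{batch}_i + \varepsilon_{ij},$$

with $\beta = \mathrm{logit}^{-1}(m)$ and two replicates adding
independent $N(0, 0.02^2)$ beta-scale noise, clipped to $[0,1]$ (noise on
the beta scale then clipping keeps the beta invariants while mimicking
array noise; clipping creates occasional exact 0/1 ties, which is why
rank-based steps treat ties explicitly).

* **Baselines** $\mu_j$ come from a three-component normal mixture on the
  logit scale with weights 0.714 / 0.156 / 0.130 and means at logit(0.10),
  logit(0.50), logit(0.90) — the unmethylated / hemi-methylated /
  methylated probe classes in the proportions reported for autosomal
  promoter arrays.
* **Co-methylation**: within a gene's probe cluster,
  $\varepsilon$ is multivariate normal with unit variance and correlation
  $\exp(-d/\ell)$ in inter-probe distance, $\ell = 1000$ bp by default — a
  one-parameter kernel whose correlation stays appreciable to roughly 2 kb,
  the scale on which neighboring CpGs covary; the implied half-distance is
  $\ell \ln 2 \approx 693$ bp, which the decay-curve estimator recovers.
* **Genotypes** are Binomial(2, f) with $f \sim U(0.05, 0.5)$ by default,
  re-labelled so MAF $\le$ 0.5, with optional first-order LD by
  neighbor-allele copying; clusters sit 200 kb apart (round-robin over 22
  autosomes) so 50 kb cis windows never overlap across genes.
* **Effects**: a fraction of probes get a causal cis SNP; effects are
  $N(0, 0.5^2)$ on the latent scale in residual-SD units (or a fixed
  magnitude with random sign via `effect_fixed`). The truth table records
  the causal SNP, the latent slope, and the standardized slope
  `slope_std` = slope / latent SD — the estimand of the association scan
  after rank normalization.
* **Confounding**: optional Gaussian latent factors with per-probe
  loadings, plus a two-level batch injected as a mean shift on a random
  probe subset, so the batch is discoverable as a leading principal
  component — emulating processing-phase structure in real studies.
* **Expression**: mediated genes get $c_j < 0$ times promoter beta with
  $|c_j|$ set so the methylation-driven component has `mediation_strength`
  times the noise SD (so effect size is controlled on the variance-
  explained scale regardless of the probe's beta spread); direct-eQTL
  genes get an analogous genotype term; values are shifted per gene to be
  non-negative, mimicking length-normalized read counts.

What the generator does **not** emulate: realistic LD maps from reference
panels, X-inactivation and imprinting, probe-level technical artefacts
(cross-hybridization, dye bias), count noise in RNA-seq, or cell-type
heterogeneity. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative assumptions, not
robustness to every artefact of real array data.

# Numerical choices and degenerate inputs

* Methylation-state boundaries are $[0, 0.3)$ / $[0.3, 0.7]$ / $(0.7, 1]$:
  the conventional description leaves 0.3 and 0.7 ambiguous, and both are
  assigned to the hemi class for a closed middle interval.
* The co-methylation decay curve uses binned weighted means of pairwise
  Spearman correlations (100 bp bins); spline smoothing is presentation-
  layer and intentionally omitted. Decay is computed on beta by default
  (the descriptive analyses precede PC correction); a residual-based run
  just passes the residual matrix. The curve is invariant to monotone
  per-individual transforms, so beta and latent-logit inputs agree.
* The TSS profile is a running median (300 bp window) over per-probe mean
  beta; medians over all individual-level values are a flag away
  (pass the full matrix of interest), and per-probe means are the default
  because they match how the profile is usually drawn.
* Rank-sum comparisons use `stats::wilcox.test`: exact null for small
  untied samples, tie-corrected normal approximation otherwise.
* `fit_additive` errors on a constant phenotype, skips constant dosages
  with the reason recorded, and requires 3 complete pairs.
* All permutation and sampling operations are seeded and bit-reproducible;
  the pipeline manifest records the config hash and seed, and reruns are
  byte-identical.
* X-chromosome association is out of scope; only autosomal SNPs enter the
  genome-wide scans (the sex-difference scan handles X-linked methylation
  descriptively).

# Problem sizes used by the validation suite

The package's checks use sizes chosen to make each property measurable
with modest Monte-Carlo error: FDR calibration on 20 studies of 500 probes
× 60 individuals (30% causal, standardized effect 0.5, 20 cis SNPs/probe,
10 permutation replicates), with realized FDP averaged over studies;
slope recovery on 4 studies of 200 causal probes at n = 200, pooled —
pooling matters because joint quantile normalization induces weak
cross-probe error correlation, making a single study's mean bias noisier
than independence would suggest; enrichment recovery on 50 replicates of
200 probes × 20 SNPs with 5× annotation enrichment; mediation detection on
one study of 150 genes at n = 150 with mediated and direct-eQTL fractions
of 0.4 each. The FDR calibration lands a point or two above the nominal
10% (the ratio estimator's conservatism and its variance at the selected
threshold pull in opposite directions), well within Monte-Carlo tolerance.

# Known limitations

* The FDR estimator with 1 trans replicate is high-variance; `n_reps` is
  configurable and more replicates are advisable when runtime allows.
* The enrichment CIs are asymptotic (see above); profile-likelihood
  intervals would be more accurate for weak signals but cost more.
* No mixed-model/kinship correction, conditional or multi-SNP models, or
  genotype imputation — dosages are consumed as given.
* IDAT parsing and array-manifest handling are out of scope; inputs are
  matrices/tables in the documented formats.
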