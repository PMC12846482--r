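---
title: "Statistical methods and design choices in growmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in growmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`growmark` implements a complete post-variant-calling analysis for finding
growth-associated SNP markers — and the subset whose superior genotypes are
confined to a single population — in a set of geographically structured
aquaculture populations. The pipeline starts from a called multi-sample VCF
and a phenotype table and runs: quality control, per-population diversity
summaries, genomic mixed-model phenotype adjustment, mixed-linear-model
GWAS, LD-based recovery of non-tag SNPs inside annotated gene windows, and
genotype-class association with superior-genotype and population-uniqueness
calls. This vignette documents the models, the parameters that matter, the
synthetic-data generator used for validation, and the design decisions made
where the analysis was genuinely open.

## The setting

The motivating design is four conservation-hatchery populations of Mandarin
fish (*Siniperca chuatsi*) sampled at different ages and sites
(20/20/20/30 individuals; baseline body weights 17.4, 18.7, 30.6 and
625.2 g). Population membership is therefore almost perfectly confounded
with age, location and season, and raw body weight differs ~35-fold between
cohorts. Every downstream choice in the package is shaped by two
consequences of this design:

* between-population weight differences are dominated by growth stage, not
  genetics, so association must run on *adjusted* phenotypes;
* the populations are genetically diverged, so naive pooled statistics
  (HWE, LD, genotype tests) absorb structure effects that need explicit
  handling.

## Quality control (`apply_filters`)

Loci are retained when **MAF > 0.1**, per-locus **missing rate < 10%** and
**Hardy-Weinberg exact-test p > 1e-6** — strict inequalities, applied
jointly, so the retained set is order-independent and filtering is
idempotent. The HWE test is the exact conditional test: given the observed
allele counts, the p-value sums the probabilities of all heterozygote
counts no more probable than the observed one. Probabilities come from the
stable mode-anchored recurrence; mathematical ties in the conditional
distribution are detected with a relative tolerance of 1e-9 so symmetric
configurations are always included together.

By default HWE is tested on **all samples pooled**, matching the combined
call-set convention of the original filtering. Pooled testing is sensitive
to population structure: a locus differentiated between populations shows a
Wahlund heterozygote deficit even when each population is internally in
equilibrium, and with hundreds of samples the exact test detects deficits
far smaller than those produced by a genuinely population-restricted
allele. `filter_config(hwe_mode = "within")` instead tests each population
separately and uses the smallest p-value, retaining differentiated but
internally conformant loci. The pooled default preserves fidelity; the
within mode is the right choice whenever population-restricted variants are
themselves targets of the analysis (it is what the planted-marker
validation below uses).

## Diversity, distances and trees (`diversity_stats`, `ibs_distance`, `neighbor_joining`)

Per-population, per-locus statistics use within-population allele
frequencies: observed heterozygosity, expected heterozygosity $2pq$,
nucleotide diversity $\pi = 2j(m-j)/(m(m-1))$ for $j$ alternate among $m$
non-missing alleles (the unbiased per-site pairwise-difference estimator),
and $\mathrm{PIC} = 1-(p^2+q^2)-2p^2q^2$. Reported values are means over
loci; monomorphic-within-population loci contribute zero by default
(whole-set averaging), with `polymorphic_only = TRUE` to exclude them.

Individual-level distance is allele sharing,
$d(i,j)=\sum |g_i-g_j| / (2L_{ij})$ over pairwise-complete loci — the
standard 1-IBS output of genotype tools. Population-level Nei standard
distance ($-\ln$ of the normalized identity) is provided separately.
Neighbor joining is the classic Saitou–Nei agglomeration with the
Q-criterion; ties are broken by the lowest index pair so output is
deterministic, and negative branch lengths are clamped to zero with the
deficit moved to the sibling edge, preserving the joined pair's path
length. On exactly additive distances the implementation reproduces the
generating topology and branch lengths.

## Phenotype adjustment (`fit_lmm_reml`, `adjust_phenotypes`)

The adjustment model is the standard animal model
$y = Xb + Za + e$, with $b$ the fixed effects (population, age, location,
season), $a \sim N(0, \sigma^2_a G)$ additive genetic effects with $G$ the
VanRaden method-1 genomic relationship matrix, and
$e \sim N(0, \sigma^2_e I)$. With no pedigree the single-step formulation
reduces to plain GBLUP with a marker GRM, and that is what is implemented.
Because the sampling covariates are confounded with population, the design
builder drops aliased columns by pivoted QR and reports them.

REML estimation profiles the restricted likelihood over the single variance
ratio $\lambda = \sigma^2_a/\sigma^2_e$ through the spectral decomposition
of $G$: in the rotated basis the covariance is diagonal, each candidate
ratio costs one weighted least-squares solve, and the optimum is found by
`optimize()` over $\log\lambda \in [-15, 15]$ with the boundary values
checked explicitly. The profiled likelihood is unimodal on all tested
problems. Degenerate perfect fits (residual variance approaching zero) are
guarded against log-of-zero.

Adjusted phenotypes come in two modes:

* **`fixed_only`** (default): $y - X\hat b$. Systematic population and
  environmental effects are removed; additive genetic signal is preserved.
* **`full_residual`**: $\hat e = y - X\hat b - \hat a$. This is the literal
  "residuals of the model", but the BLUP term $\hat a$ absorbs exactly the
  additive signal the GWAS then searches for, attenuating every marker
  effect. The mode is retained for fidelity and comparison; the default is
  the one that keeps the scan powered. This is the package's most
  consequential interpretation decision, and the attenuation is
  demonstrated in the test suite.

## GWAS (`gwas_mlm`, `merge_model_results`)

The scan is EMMAX-style: variance components are estimated once on the
null model, then every locus gets a GLS Wald t-test of its per-allele
dosage effect under the fixed covariance
$V = \hat\sigma^2_a G + \hat\sigma^2_e I$. Missing dosages are mean-imputed
per locus; loci monomorphic in the tested sample are skipped and logged.
Significance uses Bonferroni at $\alpha = 0.05$ over the loci actually
tested. With an identity kinship the test degenerates exactly to ordinary
least squares, which anchors the implementation against `lm()`.

The pipeline's per-marker model additionally includes population
indicators. The adjusted phenotype carries only within-population signal,
while a structured marker's pooled variance is substantially
between-population; conditioning on population makes the marker effect a
within-population contrast. This is ordinary stratification control, and it
is what makes effects at population-restricted loci detectable at all —
without it the between-population dosage variance dilutes the test
statistic severalfold. `gwas_mlm()` called directly defaults to an
intercept-only design, appropriate for unstructured samples.

A `loco = TRUE` option computes leave-one-chromosome-out kinships so a
marker's own polygenic contribution is never part of the covariance it is
tested against. The pipeline default remains the all-marker kinship, the
convention of the MLM implementations this package mirrors.

Merging with externally computed model results (e.g. FarmCPU and BLINK
runs, which are established published algorithms and are consumed as result
files rather than re-implemented): union by canonical locus id
`chrom_pos_ref_alt`, method labels concatenated alphabetically, stable sort
by chromosome then position. The operation is commutative and idempotent.

## Gene windows and LD expansion (`genes_near_snp`, `expand_tags`)

Because genome-wide scans conventionally thin to tag SNPs per LD segment,
true functional variants linked to a tag can be absent from the tested set.
The recovery step annotates each significant tag to genes whose bodies
intersect a ±50 kb closed window (1-based inclusive coordinates
throughout; `gene` features only), collects all SNPs inside those genes,
and flags pool members with dosage $r^2 > 0.5$ against the tag as
potentially linked. $r^2$ is the squared Pearson correlation of dosages
over pairwise-complete individuals — composite (genotypic) LD, which needs
no phasing; this is the convention of genotype-based LD tools and may
differ slightly from haplotype-EM estimates. LD is computed across all
samples pooled (structure-inflated, as in the original pooled analysis);
`ld_samples` restricts the computation to a subset, e.g. one population.
Each tag's comparisons run against its own genes' SNPs by default
(`pooled = TRUE` uses the union), same chromosome only. Tags without any
gene annotation are excluded from expansion and reported. The combined
candidate list is the union of annotated tags and newly linked SNPs; a SNP
linked to several tags keeps the best one.

## Genotype-class association (`call_markers`)

For each candidate SNP, adjusted weights are compared across genotype
classes by one-way fixed-effects ANOVA followed by Fisher's LSD (pairwise t
tests on the pooled within-class mean square, unadjusted p-values — the
classical protected-LSD protocol). Classes with fewer than `min_class_n`
(default 3) individuals are dropped from testing but kept in the frequency
tables, since rare classes still matter for uniqueness. A marker is
growth-related when the ANOVA p-value is below 0.05; **no multiplicity
correction is applied across candidates** by default, matching the plain
per-test convention of this analysis stage (a Benjamini-Hochberg option
exists; the per-test choice trades specificity for sensitivity and is
documented rather than resolved). The superior genotype is the
highest-mean eligible class — heterozygotes included — gated by ANOVA
significance; ties break by larger class size, then lexicographically, and
are flagged. The full LSD matrix is reported so stricter superiority rules
can be applied downstream. A growth-related marker is population-unique
when its superior genotype is carried in exactly one population.
Uniqueness is a statement about observed carriers, not a tested hypothesis;
with three-individual classes it is sensitive to sampling and should be
read as a screening label.

## The synthetic-data generator (`sim_config`, `simulate_genotypes`, `simulate_phenotypes`)

The generator exists so that every stage is testable without the original
resequencing data. It emulates, in order of importance:

* **Divergence**: per-locus population frequencies follow the
  Balding-Nichols model, Beta with mean equal to the ancestral frequency
  (Uniform on 0.05–0.95) and variance $F\,p(1-p)$; `fst = 0` returns the
  ancestral frequency exactly. A single-parameter, analytically checkable
  stand-in for "genetically isolated populations".
* **LD**: haplotypes are first-order Markov copy chains along each
  chromosome — each allele copies its left neighbour with probability
  `ld_rho`, otherwise draws fresh at the locus's target frequency — so
  adjacent-locus allelic correlation is ≈ `ld_rho` and genotypic
  $r^2 \approx$ `ld_rho`$^2$ regardless of frequency heterogeneity.
  (A conditional-probability chain was rejected: with widely varying
  frequencies the attainable correlation between Bernoulli variables is
  bounded well below 1, and clamping destroys the target correlation.)
  Realized per-locus frequencies are an exponentially smoothed version of
  the drawn profile, so frequency dispersion shrinks as `ld_rho` grows.
* **Planted signal**: causal loci add `effect` (in units of the common
  within-population phenotypic SD) per alternate allele; a GRM-correlated
  polygenic term takes up the remainder of `heritability`; the residual
  completes unit variance. Restricted loci are drawn at `restricted_freq`
  in the designated population and are entirely reference elsewhere; the
  chain is broken at the locus itself but downstream loci still copy from
  it, preserving local LD around the planted marker.
* **Confounding**: observed weight is
  `population_mean + covariate effects + within_sd * z`, with age, location
  and season assigned per population exactly as in the field design (fully
  aliased with population). The study reports only mean ± spread per
  cohort, so the within-population SD is a single free parameter
  (`within_sd`, default 5 g — the order of the smaller cohorts' spreads). A
  common within-population scale keeps pooled association well-posed;
  per-cohort scales as printed would let the largest cohort's residual
  variance dominate every pooled test statistic. This simplification, and
  the absence of coalescent realism, genotyping error and non-uniform
  missingness (missingness is injected uniformly at 2% by default), bound
  what passing tests show about real data: calibration and recovery hold
  under the generator's idealized structure, not necessarily under real
  LD landscapes or cohort-specific variance heterogeneity.

Seeded runs are byte-identical; genotypes and phenotypes derive their
randomness from `seed` and `seed + 1` respectively.

## Validation design and problem sizes

The test suite and `scripts/acceptance.R` validate the pipeline at sizes a
single desktop core handles comfortably:

* worked examples computable from published per-model significant-locus
  lists and substitution-class counts (shipped under `inst/extdata/`);
* exact-equivalence sweeps: the HWE test against exhaustive enumeration for
  all genotype triples with $N \le 30$; dosage $r^2$ against the direct
  covariance formula on 1000 random pairs; identity-kinship GWAS against
  OLS on a 200 × 500 problem; NJ against 100 random additive trees;
* a planted end-to-end study: four populations of 100, 5000 loci,
  `ld_rho = 0.894` (adjacent $r^2 \approx 0.8$), one 0.8-SD causal tag
  whose alternate allele is confined to HLJ at frequency 0.6, pooled MAF
  ≈ 0.15. Recovery means the planted marker appears in the final
  population-unique report attributed to HLJ. This scenario uses
  `hwe_mode = "within"`: a deliberately population-restricted allele
  violates pooled HWE *by construction* (Wahlund deficit, exact-test
  p ≈ 1e-17 at n = 400), and the validation targets the association and
  classification stages, with the QC filter validated separately.
* the family-wise error rate of the GWAS stage, measured on the same
  scenario with **no genetic contribution at all** (`heritability = 0`).
  Under a polygenic background simulated from the tested markers every
  marker carries a share of real genetic variance, so a genome-wide "false
  positive" would be undefined; with $h^2 = 0$ type-I error is
  well-defined and Bonferroni control holds.

## Numerical choices

* REML: `optimize()` tolerance 1e-8 on $\log\lambda$; eigenvalues clipped
  at zero; boundary candidates always evaluated.
* HWE ties: relative tolerance 1e-9 (see above).
* NJ: Q-matrix ties resolved to the lowest index pair; branch lengths
  serialized at 12 significant digits.
* p-values of the GLS Wald test use $t$ with $n - q - 1$ degrees of
  freedom and are floored at the smallest positive double.
* Dosage matrices are plain numeric matrices; all pairwise operations
  (IBS, LD) handle missingness by pairwise-complete masks computed with
  matrix products rather than per-pair loops.

## Known limitations

* FarmCPU/BLINK are consumed as external result files, never re-run.
* ADMIXTURE-style ancestry inference, GO/KEGG enrichment and plot
  rendering are out of scope; outputs are TSV/Newick/JSON.
* The HWE filter's pooled default and the LD step's pooled default both
  inherit structure sensitivity from the original analysis; the
  structure-aware alternatives are provided but not default.
* Population-uniqueness is an observational label (see above), and at
  study-scale class sizes the superior-genotype call itself can rest on
  three individuals.
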