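#' Simulation configuration for structured-population genotype/phenotype data
#'
#' Defaults emulate the study design the downstream inference assumes: four
#' diverged populations (HLJ, AH, HN, HB) of 20/20/20/30 fish sampled at
#' different growth stages, so baseline weights differ by more than an order
#' of magnitude and population is confounded with age, location and season.
#'
#' @param n_per_population named integer vector of individuals per population.
#' @param n_chromosomes number of chromosomes.
#' @param loci_per_chromosome SNP loci per chromosome, spaced `locus_spacing`
#'   bp apart.
#' @param fst Balding-Nichols divergence parameter in `[0, 1)`; scalar or one
#'   value per population.
#' @param ld_rho adjacent-locus haplotype allele correlation in `[0, 1)`;
#'   adjacent-locus genotypic r-squared is approximately `ld_rho^2`.
#' @param causal_spec data.frame with columns `locus` (global locus index)
#'   and `effect` (additive effect per alternate allele, in units of the
#'   within-population phenotypic SD), or NULL.
#' @param restricted_spec data.frame with columns `locus` and `population`
#'   (label or index): the alternate allele at these loci occurs only in the
#'   designated population. A locus may appear in both `causal_spec` and
#'   `restricted_spec` (a population-restricted causal marker).
#' @param restricted_freq alternate-allele frequency used inside the
#'   designated population at restricted loci.
#' @param heritability narrow-sense h2 in `[0, 1]` of the within-population
#'   phenotype: the causal loci take their share, the remainder is a
#'   GRM-correlated polygenic term.
#' @param population_means baseline body weight (g) per population.
#' @param within_sd common within-population phenotypic SD in grams. The
#'   study reports only mean +/- spread per sampling stage; a single free
#'   parameter is exposed rather than a per-population value.
#' @param covariate_effects named numeric, currently `age` (g per month of
#'   age beyond the youngest cohort).
#' @param missing_rate genotype missingness injected uniformly at random.
#' @param locus_spacing distance in bp between adjacent loci.
#' @param gene_length,gene_spacing geometry of the synthetic genes tiling
#'   each chromosome in the emitted GFF3.
#' @param maf_range range of ancestral allele frequencies (Uniform draw),
#'   bounded away from 0/1 to avoid degenerate loci.
#' @param seed integer seed; all simulation randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_population = c(HLJ = 20L, AH = 20L, HN = 20L, HB = 30L),
                       n_chromosomes = 5L,
                       loci_per_chromosome = 200L,
                       fst = 0.1,
                       ld_rho = 0.5,
                       causal_spec = NULL,
                       restricted_spec = NULL,
                       restricted_freq = 0.5,
                       heritability = 0.3,
                       population_means = c(17.4, 18.7, 30.6, 625.2),
                       within_sd = 5,
                       covariate_effects = c(age = 0),
                       missing_rate = 0.02,
                       locus_spacing = 1000L,
                       gene_length = 30000L,
                       gene_spacing = 40000L,
                       maf_range = c(0.05, 0.95),
                       seed = 1L) {
  if (is.null(names(n_per_population))) {
    names(n_per_population) <- paste0("pop", seq_along(n_per_population))
  }
  n_pops <- length(n_per_population)
  n_loci <- n_chromosomes * loci_per_chromosome
  if (missing(population_means) && n_pops != length(population_means)) {
    # study-shaped default only fits four populations; otherwise a flat
    # 100 g baseline per population
    population_means <- rep(100, n_pops)
  }
  stopifnot(
    all(n_per_population >= 1L),
    all(fst >= 0), all(fst < 1),
    length(fst) %in% c(1L, n_pops),
    ld_rho >= 0, ld_rho < 1,
    heritability >= 0, heritability <= 1,
    length(population_means) == n_pops,
    within_sd >= 0,
    missing_rate >= 0, missing_rate < 1,
    maf_range[1] > 0, maf_range[2] < 1
  )
  check_spec <- function(spec, cols) {
    if (is.null(spec)) return(NULL)
    spec <- as.data.frame(spec)
    stopifnot(all(cols %in% names(spec)))
    if (any(spec$locus < 1L | spec$locus > n_loci)) {
      stop("locus index out of range 1..", n_loci)
    }
    spec
  }
  causal_spec <- check_spec(causal_spec, c("locus", "effect"))
  restricted_spec <- check_spec(restricted_spec, c("locus", "population"))
  if (!is.null(restricted_spec)) {
    if (is.character(restricted_spec$population)) {
      idx <- match(restricted_spec$population, names(n_per_population))
      if (anyNA(idx)) stop("unknown population in restricted_spec")
      restricted_spec$population <- idx
    }
    stopifnot(all(restricted_spec$population %in% seq_len(n_pops)))
  }
  structure(
    list(
      n_per_population = n_per_population,
      n_populations = n_pops,
      n_chromosomes = as.integer(n_chromosomes),
      loci_per_chromosome = as.integer(loci_per_chromosome),
      fst = rep_len(fst, n_pops),
      ld_rho = ld_rho,
      causal_spec = causal_spec,
      restricted_spec = restricted_spec,
      restricted_freq = restricted_freq,
      heritability = heritability,
      population_means = unname(population_means),
      within_sd = within_sd,
      covariate_effects = covariate_effects,
      missing_rate = missing_rate,
      locus_spacing = as.integer(locus_spacing),
      gene_length = as.integer(gene_length),
      gene_spacing = as.integer(gene_spacing),
      maf_range = maf_range,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Balding-Nichols population allele frequencies
#'
#' Draws one alternate-allele frequency per population from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`. `fst = 0` returns `p` exactly for every population.
#'
#' @param ancestral_freq ancestral alternate-allele frequency, strictly
#'   inside (0, 1).
#' @param fst divergence parameter(s) in `[0, 1)`; recycled to
#'   `n_populations`.
#' @param n_populations number of populations to draw.
#' @return Numeric vector of length `n_populations`.
#' @export
draw_population_freqs <- function(ancestral_freq, fst, n_populations = length(fst)) {
  if (ancestral_freq <= 0 || ancestral_freq >= 1) {
    stop("degenerate locus: ancestral_freq must be strictly inside (0, 1)")
  }
  stopifnot(all(fst >= 0), all(fst < 1), n_populations >= 1L)
  fst <- rep_len(fst, n_populations)
  out <- numeric(n_populations)
  zero <- fst == 0
  out[zero] <- ancestral_freq
  if (any(!zero)) {
    f <- fst[!zero]
    out[!zero] <- stats::rbeta(sum(!zero),
                               ancestral_freq * (1 - f) / f,
                               (1 - ancestral_freq) * (1 - f) / f)
  }
  out
}

# One Markov haplotype chain block: H haplotypes x L loci. Each allele is
# copied from the previous locus with probability rho and freshly drawn from
# the locus's target frequency otherwise, so adjacent-locus allelic
# correlation is ~rho regardless of frequency heterogeneity (a
# copy/recombination chain; realized frequencies are an exponentially
# smoothed version of the target profile). Loci flagged in `fresh` always
# draw from their target frequency, breaking the chain there.
markov_haplotypes <- function(H, p, rho, fresh = logical(length(p))) {
  L <- length(p)
  h <- matrix(0L, nrow = H, ncol = L)
  h[, 1L] <- stats::rbinom(H, 1L, p[1L])
  if (L > 1L) {
    for (l in 2L:L) {
      draw <- stats::rbinom(H, 1L, p[l])
      if (fresh[l] || rho == 0) {
        h[, l] <- draw
      } else {
        copy <- stats::runif(H) < rho
        h[, l] <- ifelse(copy, h[, l - 1L], draw)
      }
    }
  }
  h
}

#' Simulate genotypes for diverged, LD-structured populations
#'
#' Ancestral frequencies are Uniform over `maf_range`; per-population
#' frequencies follow the Balding-Nichols model; haplotypes are first-order
#' Markov chains along each chromosome so adjacent loci have allelic
#' correlation about `ld_rho`; genotypes are sums of two independent
#' haplotypes. Population-restricted loci carry the alternate allele only in
#' the designated population (frequency `restricted_freq` there, zero
#' elsewhere); missing genotypes are injected uniformly at `missing_rate`.
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A `variant_table` with population labels. Per-population allele
#'   frequencies used by the generator are attached as attribute
#'   `pop_freqs` (populations x loci).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pops <- config$n_populations
  L <- config$n_chromosomes * config$loci_per_chromosome
  anc <- stats::runif(L, config$maf_range[1], config$maf_range[2])
  P <- matrix(0, nrow = n_pops, ncol = L)
  for (k in seq_len(n_pops)) {
    P[k, ] <- vapply(anc, function(p) {
      draw_population_freqs(p, config$fst[k], 1L)
    }, numeric(1L))
  }
  fresh <- logical(L)
  if (!is.null(config$restricted_spec)) {
    for (r in seq_len(nrow(config$restricted_spec))) {
      l <- config$restricted_spec$locus[r]
      k <- config$restricted_spec$population[r]
      # restricted loci are drawn at their exact target frequency (chain
      # broken at the locus) so the designated population carries the
      # alternate allele at restricted_freq and the others not at all;
      # downstream loci still copy from them, preserving local LD
      P[, l] <- 0
      P[k, l] <- config$restricted_freq
      fresh[l] <- TRUE
    }
  }
  chrom <- rep(paste0("Chr", seq_len(config$n_chromosomes)),
               each = config$loci_per_chromosome)
  pos <- rep(seq_len(config$loci_per_chromosome) * config$locus_spacing,
             times = config$n_chromosomes)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1L))
  dos <- matrix(NA_real_, nrow = sum(config$n_per_population), ncol = L)
  pops <- rep(names(config$n_per_population), times = config$n_per_population)
  row0 <- 0L
  for (k in seq_len(n_pops)) {
    n_k <- config$n_per_population[k]
    rows <- row0 + seq_len(n_k)
    for (c_i in seq_len(config$n_chromosomes)) {
      cols <- (c_i - 1L) * config$loci_per_chromosome +
        seq_len(config$loci_per_chromosome)
      h1 <- markov_haplotypes(n_k, P[k, cols], config$ld_rho, fresh[cols])
      h2 <- markov_haplotypes(n_k, P[k, cols], config$ld_rho, fresh[cols])
      dos[rows, cols] <- h1 + h2
    }
    row0 <- row0 + n_k
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_real_
  }
  rownames(dos) <- sprintf("%s_%02d", pops,
                           unlist(lapply(config$n_per_population, seq_len)))
  tab <- variant_table(
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    dos, populations = pops
  )
  attr(tab, "pop_freqs") <- P
  attr(tab, "ancestral_freqs") <- anc
  tab
}

#' Simulate body-weight phenotypes with population confounding
#'
#' Within-population phenotype (in SD units) is the sum of planted causal
#' effects, a GRM-correlated polygenic term and an independent residual; the
#' causal plus polygenic share of variance equals `heritability`. Observed
#' weight is `population_mean + covariate effects + within_sd * z`, so
#' between-population differences (growth stage, location, season) dominate
#' the raw phenotype as in the sampled field populations.
#'
#' @param genotypes a `variant_table` from [simulate_genotypes()].
#' @param config the matching [sim_config()].
#' @return data.frame (PhenotypeTable) with columns `id`, `population`,
#'   `weight_g`, `age`, `location`, `season`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- n_individuals(genotypes)
  pops <- genotypes$populations
  pop_idx <- match(pops, names(config$n_per_population))
  g_causal <- rep(0, n)
  var_causal <- 0
  if (!is.null(config$causal_spec) && nrow(config$causal_spec) > 0L) {
    for (r in seq_len(nrow(config$causal_spec))) {
      l <- config$causal_spec$locus[r]
      beta <- config$causal_spec$effect[r]
      d <- genotypes$dosage[, l]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      g_causal <- g_causal + beta * (d - mean(d))
      # pooled within-population dosage variance: the share of the
      # within-population phenotypic variance this locus explains
      v_within <- stats::weighted.mean(
        tapply(d, pops, stats::var),
        table(pops)[names(tapply(d, pops, stats::var))]
      )
      if (is.na(v_within)) v_within <- 0
      var_causal <- var_causal + beta^2 * v_within
    }
  }
  h2 <- config$heritability
  if (var_causal > 1) {
    stop("configured causal effects exceed total within-population variance")
  }
  var_poly <- max(h2 - var_causal, 0)
  var_resid <- 1 - var_causal - var_poly
  if (var_resid < 0) var_resid <- 0
  if (var_poly + var_causal + var_resid < .Machine$double.eps) {
    stop("degenerate configuration: zero causal, polygenic and residual variance")
  }
  a <- rep(0, n)
  if (var_poly > 0) {
    G <- compute_grm(genotypes)
    Lc <- chol(G + diag(1e-6, n))
    a <- sqrt(var_poly) * drop(crossprod(Lc, stats::rnorm(n)))
  }
  e <- stats::rnorm(n, sd = sqrt(var_resid))
  z <- g_causal + a + e
  # per-population age (months) and sampling metadata, fully confounded with
  # population as in the field sampling design
  ages <- c(6, 7, 7, 10)[((pop_idx - 1L) %% 4L) + 1L]
  seasons <- c("Jun", "Jul", "Jul", "Oct")[((pop_idx - 1L) %% 4L) + 1L]
  age_eff <- if ("age" %in% names(config$covariate_effects)) {
    config$covariate_effects[["age"]] * (ages - min(ages))
  } else 0
  weight <- config$population_means[pop_idx] + age_eff + config$within_sd * z
  data.frame(
    id = rownames(genotypes$dosage),
    population = pops,
    weight_g = weight,
    age = ages,
    location = pops,
    season = seasons,
    stringsAsFactors = FALSE
  )
}

#' Write simulated genotypes, phenotypes and gene annotation to disk
#'
#' Emits a VCF 4.2 (gzip), a phenotype TSV and a GFF3 whose synthetic gene
#' features tile each chromosome (`gene_length` bp every `gene_spacing` bp),
#' so window-based gene annotation downstream is exercised.
#'
#' @param genotypes a `variant_table`.
#' @param phenotypes a phenotype data.frame from [simulate_phenotypes()].
#' @param config the matching [sim_config()].
#' @param dir output directory (created if needed).
#' @return Named list of file paths (`vcf`, `pheno`, `gff`).
#' @export
write_sim_outputs <- function(genotypes, phenotypes, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf_path <- write_vcf(genotypes, file.path(dir, "genotypes.vcf.gz"))
  pheno_path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(phenotypes, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gff_path <- file.path(dir, "genes.gff3")
  genes <- synthetic_gene_models(config)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    type = "gene",
    source = "growmark",
    ID = genes$gene_id
  )
  rtracklayer::export(gr, gff_path, format = "gff3")
  list(vcf = vcf_path, pheno = pheno_path, gff = gff_path)
}

#' Synthetic gene models tiling the simulated chromosomes
#'
#' @param config a [sim_config()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
synthetic_gene_models <- function(config) {
  chrom_len <- config$loci_per_chromosome * config$locus_spacing
  starts <- seq.int(1L, chrom_len, by = config$gene_spacing)
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(c_i) {
    data.frame(
      gene_id = sprintf("gene_Chr%d_%03d", c_i, seq_along(starts)),
      chrom = paste0("Chr", c_i),
      start = starts,
      end = pmin(starts + config$gene_length - 1L, chrom_len),
      strand = "+",
      stringsAsFactors = FALSE
    )
  }))
}
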