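#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or the triple
#' `vcf`/`pheno`/`gff` file paths must be supplied. Stage parameter defaults
#' are the analysis settings documented in the methods vignette.
#'
#' @param sim optional [sim_config()]; when given, inputs are simulated.
#' @param vcf,pheno,gff input file paths (VCF, phenotype TSV with columns
#'   id/population/weight_g/..., GFF3) when not simulating.
#' @param external_results optional named character vector of per-model
#'   significant-locus TSV paths (e.g. FarmCPU/BLINK results computed
#'   elsewhere); each file needs `snp` and `method` columns.
#' @param filter a [filter_config()].
#' @param covariates fixed-effect columns of the phenotype table used in the
#'   adjustment model.
#' @param adjust_mode see [adjust_phenotypes()].
#' @param alpha_gwas Bonferroni family-wise level for the GWAS stage.
#' @param window gene-annotation half-window (bp).
#' @param r2_min LD threshold for tag expansion.
#' @param alpha_assoc per-test level of the genotype-class ANOVA.
#' @param min_class_n minimum genotype-class size in the ANOVA.
#' @param skip character vector of stage names to skip (subset of
#'   "popgen"); core stages always run.
#' @param write_files if FALSE, no stage output files are written (results
#'   are only returned); useful for simulation studies.
#' @param seed integer seed recorded in the manifest and used for
#'   simulation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, pheno = NULL, gff = NULL,
                            external_results = NULL,
                            filter = filter_config(),
                            covariates = c("population", "age", "location", "season"),
                            adjust_mode = "fixed_only",
                            alpha_gwas = 0.05,
                            window = 50000L,
                            r2_min = 0.5,
                            alpha_assoc = 0.05,
                            min_class_n = 3L,
                            skip = character(0),
                            write_files = TRUE,
                            seed = 1L) {
  have_sim <- !is.null(sim)
  have_files <- !is.null(vcf) && !is.null(pheno) && !is.null(gff)
  if (have_sim == have_files) {
    stop("supply exactly one of: a simulation config, or vcf + pheno + gff paths")
  }
  if (have_sim) stopifnot(inherits(sim, "sim_config"))
  stopifnot(alpha_gwas > 0, alpha_gwas < 1, alpha_assoc > 0, alpha_assoc < 1,
            window >= 0, r2_min >= 0, r2_min < 1)
  structure(
    list(sim = sim, vcf = vcf, pheno = pheno, gff = gff,
         external_results = external_results, filter = filter,
         covariates = covariates, adjust_mode = adjust_mode,
         alpha_gwas = alpha_gwas, window = as.integer(window),
         r2_min = r2_min, alpha_assoc = alpha_assoc,
         min_class_n = as.integer(min_class_n), skip = skip,
         write_files = write_files, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim` block
#' is passed to [sim_config()] (with `causal_spec`/`restricted_spec` given
#' as lists of records).
#'
#' @param path YAML file path.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    sim_args <- raw$sim
    for (f in c("causal_spec", "restricted_spec")) {
      if (!is.null(sim_args[[f]])) {
        sim_args[[f]] <- do.call(rbind, lapply(sim_args[[f]], as.data.frame))
      }
    }
    if (!is.null(sim_args$n_per_population)) {
      sim_args$n_per_population <- unlist(sim_args$n_per_population)
    }
    raw$sim <- do.call(sim_config, sim_args)
  }
  if (!is.null(raw$filter)) raw$filter <- do.call(filter_config, raw$filter)
  do.call(pipeline_config, raw)
}

#' Run the full marker-discovery pipeline
#'
#' Stages, each consuming the previous stage's output: acquire (simulate or
#' read VCF/phenotype/GFF3), QC filter, population-genetic summaries
#' (diversity, IBS distances, NJ tree), genomic mixed-model phenotype
#' adjustment, EMMAX-style GWAS with Bonferroni control, multi-model merge
#' (with optional external FarmCPU/BLINK result files), gene-window LD
#' expansion of the significant tags, and genotype-class association with
#' superior-genotype and population-uniqueness calls. A JSON manifest
#' records package version, parameters, seed, per-stage row counts and
#' checksums of written files. Any stage failure aborts with the stage name;
#' files written by earlier stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list of class `pipeline_result` with elements `genotypes`,
#'   `phenotypes`, `filtered`, `audit`, `diversity`, `tree`, `grm`, `fit`,
#'   `adjusted`, `gwas`, `merged`, `expansion`, `calls`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("growmark_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "growmark",
    version = as.character(utils::packageVersion("growmark")),
    seed = config$seed,
    parameters = list(
      maf_min = config$filter$maf_min,
      max_missing = config$filter$max_missing,
      hwe_p_min = config$filter$hwe_p_min,
      hwe_mode = config$filter$hwe_mode,
      covariates = config$covariates,
      adjust_mode = config$adjust_mode,
      alpha_gwas = config$alpha_gwas,
      window = config$window,
      r2_min = config$r2_min,
      alpha_assoc = config$alpha_assoc,
      min_class_n = config$min_class_n
    ),
    stages = list(),
    files = list()
  )
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- acquire ----------------------------------------------------------
  if (!is.null(config$sim)) {
    genotypes <- stage("simulate", simulate_genotypes(config$sim))
    phenotypes <- stage("simulate", simulate_phenotypes(genotypes, config$sim))
    genes <- synthetic_gene_models(config$sim)
    if (config$write_files) {
      paths <- write_sim_outputs(genotypes, phenotypes, config$sim,
                                 file.path(out_dir, "input"))
      written <- c(written, unlist(paths))
    }
  } else {
    phenotypes <- stage("read_inputs",
                        as.data.frame(data.table::fread(config$pheno)))
    pops <- stats::setNames(phenotypes$population, phenotypes$id)
    genotypes <- stage("read_inputs", read_vcf(config$vcf, populations = pops))
    phenotypes <- phenotypes[match(rownames(genotypes$dosage), phenotypes$id), ]
    genes <- stage("read_inputs", read_gene_models(config$gff))
  }
  manifest$stages$acquire <- list(
    n_individuals = n_individuals(genotypes),
    n_loci = n_loci(genotypes),
    n_genes = nrow(genes)
  )

  # -- QC filter --------------------------------------------------------
  filt <- stage("varfilter", apply_filters(genotypes, config$filter))
  filtered <- filt$table
  manifest$stages$varfilter <- list(
    n_input = n_loci(genotypes),
    n_retained = n_loci(filtered),
    n_dropped = n_loci(genotypes) - n_loci(filtered)
  )
  if (config$write_files) {
    audit_path <- file.path(out_dir, "filter_audit.tsv")
    utils::write.table(filt$audit, audit_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    subs <- summarize_substitution_classes(filtered)
    subs_path <- file.path(out_dir, "substitution_summary.tsv")
    utils::write.table(subs$by_class, subs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    vcf_path <- write_vcf(filtered, file.path(out_dir, "filtered.vcf.gz"))
    written <- c(written, audit_path, subs_path, vcf_path)
  }

  # -- population genetics ---------------------------------------------
  diversity <- NULL; tree <- NULL
  if (!"popgen" %in% config$skip) {
    diversity <- stage("popgen", diversity_stats(filtered))
    dmat <- stage("popgen", ibs_distance(filtered))
    tree <- stage("popgen", neighbor_joining(dmat))
    manifest$stages$popgen <- list(n_populations = nrow(diversity))
    if (config$write_files) {
      div_path <- file.path(out_dir, "diversity.tsv")
      utils::write.table(diversity, div_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      dist_path <- file.path(out_dir, "ibs_distance.tsv")
      utils::write.table(round(dmat, 6), dist_path, sep = "\t", quote = FALSE)
      tree_path <- file.path(out_dir, "nj_tree.nwk")
      ape::write.tree(tree, tree_path)
      written <- c(written, div_path, dist_path, tree_path)
    }
  }

  # -- mixed model: adjustment + GWAS ----------------------------------
  grm <- stage("mixedmodel", compute_grm(filtered))
  X <- stage("mixedmodel", build_design(phenotypes, config$covariates))
  fit <- stage("mixedmodel", fit_lmm_reml(phenotypes$weight_g, X, grm))
  adjusted <- stage("mixedmodel", adjust_phenotypes(fit, config$adjust_mode))
  # per-marker model includes population indicators so the marker effect is
  # a within-population contrast: protects against residual stratification
  # and is required for loci whose variation is confined to one population
  X_gwas <- if (length(unique(phenotypes$population)) > 1L) {
    stage("gwas", build_design(phenotypes, "population"))
  } else NULL
  gwas <- stage("gwas", gwas_mlm(adjusted, filtered, grm,
                                 alpha = config$alpha_gwas, X = X_gwas))
  manifest$stages$mixedmodel <- list(
    sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e,
    adjust_mode = config$adjust_mode,
    m_tested = attr(gwas, "m_tested"),
    bonferroni_threshold = attr(gwas, "threshold"),
    n_significant = sum(gwas$significant)
  )
  external <- list()
  if (!is.null(config$external_results)) {
    external <- stage("merge", lapply(config$external_results, function(p) {
      as.data.frame(data.table::fread(p))
    }))
  }
  sig <- gwas[gwas$significant, c("snp", "method"), drop = FALSE]
  merged <- stage("merge", merge_model_results(c(list(sig), external)))
  manifest$stages$merge <- list(n_models = 1L + length(external),
                                n_merged = nrow(merged))
  if (config$write_files) {
    gwas_path <- file.path(out_dir, "gwas_results.tsv")
    utils::write.table(as.data.frame(gwas), gwas_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    merged_path <- file.path(out_dir, "merged_significant_loci.tsv")
    utils::write.table(merged, merged_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, gwas_path, merged_path)
  }

  # -- linkmap: gene annotation + LD expansion -------------------------
  tags <- intersect(merged$SNP, filtered$loci$id)
  expansion <- stage("linkmap", expand_tags(tags, filtered, genes,
                                            window = config$window,
                                            r2_min = config$r2_min))
  manifest$stages$linkmap <- list(
    n_tags = length(tags),
    n_annotated_tags = length(tags) - length(expansion$unannotated_tags),
    n_candidates = nrow(expansion$combined),
    n_linked = sum(expansion$combined$source == "linked")
  )
  if (config$write_files && nrow(expansion$combined) > 0L) {
    linked_path <- file.path(out_dir, "linked_snps.tsv")
    utils::write.table(expansion$combined, linked_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, linked_path)
  }

  # -- assoc: genotype-class association -------------------------------
  calls <- stage("assoc", call_markers(
    filtered, expansion$combined$snp, adjusted,
    alpha = config$alpha_assoc, min_class_n = config$min_class_n
  ))
  manifest$stages$assoc <- list(
    n_candidates = nrow(calls),
    n_growth_related = sum(calls$growth_related),
    n_population_unique = sum(calls$population_unique)
  )
  if (config$write_files) {
    paths <- report_markers(calls, out_dir)
    written <- c(written, unlist(paths))
  }

  manifest$files <- if (length(written) > 0L) {
    sums <- tools::md5sum(written)
    mapply(function(p, s) list(path = p, md5 = unname(s), bytes = file.size(p)),
           written, sums, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  } else list()
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  structure(
    list(genotypes = genotypes, phenotypes = phenotypes, filtered = filtered,
         audit = filt$audit, diversity = diversity, tree = tree, grm = grm,
         fit = fit, adjusted = adjusted, gwas = gwas, merged = merged,
         expansion = expansion, calls = calls, manifest = manifest,
         out_dir = out_dir),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("growmark pipeline run\n")
  cat("  loci:", x$manifest$stages$varfilter$n_input, "->",
      x$manifest$stages$varfilter$n_retained, "after QC\n")
  cat("  GWAS significant:", x$manifest$stages$mixedmodel$n_significant,
      "| merged:", x$manifest$stages$merge$n_merged, "\n")
  cat("  candidates:", x$manifest$stages$assoc$n_candidates,
      "| growth-related:", x$manifest$stages$assoc$n_growth_related,
      "| population-unique:", x$manifest$stages$assoc$n_population_unique, "\n")
  invisible(x)
}
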