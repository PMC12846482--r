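#' Genotype class labels for a biallelic SNP
#'
#' Dosage 0 is the reference homozygote, 1 the ref/alt heterozygote and 2
#' the alternate homozygote; labels concatenate the alleles (e.g. "AG" at an
#' A -> G SNP).
#'
#' @param ref,alt single nucleotides.
#' @return Character vector of length 3 named "0", "1", "2".
#' @export
genotype_class_labels <- function(ref, alt) {
  stats::setNames(c(paste0(ref, ref), paste0(ref, alt), paste0(alt, alt)),
                  c("0", "1", "2"))
}

#' One-way ANOVA with Fisher's LSD post-hoc tests
#'
#' Classes with fewer than `min_class_n` observations are dropped before
#' testing. If at least two classes remain, a fixed-effects one-way ANOVA
#' (F with k-1 and N-k df) is computed, followed by LSD pairwise t tests
#' using the pooled within-class mean square and N-k df, with unadjusted
#' p-values. With fewer than two eligible classes the marker is flagged not
#' testable rather than raising an error.
#'
#' @param weights numeric response (e.g. adjusted body weight).
#' @param classes character genotype-class labels, same length as `weights`;
#'   NAs dropped pairwise.
#' @param min_class_n minimum class size to enter the ANOVA (default 3).
#' @return list with `status` ("ok"/"not_testable"), `F`, `p`, `df`,
#'   `class_stats` (data.frame: `class`, `n`, `mean`), `lsd` (symmetric
#'   matrix of pairwise p-values) and `dropped_classes`.
#' @export
anova_lsd <- function(weights, classes, min_class_n = 3L) {
  ok <- !is.na(weights) & !is.na(classes)
  w <- weights[ok]
  cls <- as.character(classes[ok])
  counts <- base::table(cls)
  eligible <- names(counts)[counts >= min_class_n]
  dropped <- setdiff(names(counts), eligible)
  keep <- cls %in% eligible
  w <- w[keep]
  cls <- factor(cls[keep])
  class_stats <- data.frame(
    class = levels(cls),
    n = as.integer(base::table(cls)),
    mean = as.numeric(tapply(w, cls, mean)),
    stringsAsFactors = FALSE
  )
  if (nlevels(cls) < 2L) {
    return(list(status = "not_testable", F = NA_real_, p = NA_real_,
                df = c(NA_integer_, NA_integer_),
                class_stats = class_stats,
                lsd = NULL, dropped_classes = dropped))
  }
  an <- stats::anova(stats::lm(w ~ cls))
  fval <- an$`F value`[1L]
  pval <- an$`Pr(>F)`[1L]
  mse <- an$`Mean Sq`[2L]
  df2 <- an$Df[2L]
  k <- nlevels(cls)
  lsd <- matrix(NA_real_, k, k,
                dimnames = list(class_stats$class, class_stats$class))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tij <- (class_stats$mean[i] - class_stats$mean[j]) /
        sqrt(mse * (1 / class_stats$n[i] + 1 / class_stats$n[j]))
      pij <- 2 * stats::pt(-abs(tij), df = df2)
      lsd[i, j] <- lsd[j, i] <- pij
    }
  }
  diag(lsd) <- 1
  list(status = "ok", F = fval, p = pval, df = c(an$Df[1L], df2),
       class_stats = class_stats, lsd = lsd, dropped_classes = dropped)
}

#' Call the superior genotype of a growth-related marker
#'
#' When the ANOVA p-value is below `alpha`, the superior genotype is the
#' eligible class with the highest mean adjusted weight (heterozygotes are
#' eligible). Ties are broken by larger class size, then lexicographically,
#' and flagged. Non-significant markers get no superior genotype.
#'
#' @param test result of [anova_lsd()].
#' @param alpha significance gate (default 0.05).
#' @return Superior class label, or `NA_character_`; attribute `tie` is TRUE
#'   when the argmax was tied on the mean.
#' @export
call_superior_genotype <- function(test, alpha = 0.05) {
  if (!identical(test$status, "ok") || is.na(test$p) || test$p >= alpha) {
    return(NA_character_)
  }
  cs <- test$class_stats
  top <- cs[cs$mean == max(cs$mean), , drop = FALSE]
  tie <- nrow(top) > 1L
  top <- top[order(-top$n, top$class), , drop = FALSE]
  out <- top$class[1L]
  attr(out, "tie") <- tie
  out
}

#' Per-population genotype-class counts and frequencies at one SNP
#'
#' Frequencies are over non-missing individuals within each population and
#' sum to 1 per population; populations with no called genotype at the SNP
#' get an all-NA frequency row.
#'
#' @param dosages dosage vector (0/1/2/NA).
#' @param populations population labels.
#' @param ref,alt alleles used to render class labels.
#' @return list with `counts` and `freqs`: populations x classes matrices.
#' @export
genotype_freqs_by_population <- function(dosages, populations, ref, alt) {
  labels <- genotype_class_labels(ref, alt)
  pops <- unique(populations)
  counts <- matrix(0L, nrow = length(pops), ncol = 3L,
                   dimnames = list(pops, unname(labels)))
  for (pk in pops) {
    d <- dosages[populations == pk]
    counts[pk, ] <- c(sum(d == 0, na.rm = TRUE),
                      sum(d == 1, na.rm = TRUE),
                      sum(d == 2, na.rm = TRUE))
  }
  totals <- rowSums(counts)
  freqs <- counts / ifelse(totals == 0, NA_real_, totals)
  if (any(totals == 0)) {
    message("genotype_freqs_by_population: population(s) with no called ",
            "genotypes: ", paste(pops[totals == 0], collapse = ", "))
  }
  list(counts = counts, freqs = freqs)
}

#' Population uniqueness of a superior genotype
#'
#' A marker is population-unique when its superior genotype is carried
#' (frequency > 0) in exactly one population.
#'
#' @param counts populations x classes count matrix (see
#'   [genotype_freqs_by_population()]).
#' @param superior superior genotype class label.
#' @return list with `unique` (logical) and `population` (label or NA).
#' @export
classify_population_unique <- function(counts, superior) {
  if (is.na(superior)) return(list(unique = FALSE, population = NA_character_))
  if (!superior %in% colnames(counts)) {
    stop("superior genotype ", superior, " absent from the class table")
  }
  present <- rownames(counts)[counts[, superior] > 0]
  if (length(present) == 0L) {
    stop("superior genotype ", superior,
         " not observed in any population (inconsistent call)")
  }
  list(unique = length(present) == 1L,
       population = if (length(present) == 1L) present else NA_character_)
}

#' Genotype-class association of candidate SNPs with adjusted weight
#'
#' Runs [anova_lsd()], [call_superior_genotype()],
#' [genotype_freqs_by_population()] and [classify_population_unique()] for
#' each candidate SNP. By design no multiplicity correction is applied
#' across candidates (plain per-test p < alpha); `p_adjust = "BH"` enables
#' Benjamini-Hochberg control of the growth-related calls instead.
#'
#' @param table a filtered `variant_table`.
#' @param candidates character vector of candidate SNP ids present in
#'   `table`.
#' @param weights adjusted phenotype vector (same individuals as `table`).
#' @param populations population labels (defaults to `table$populations`).
#' @param alpha per-test significance level (default 0.05).
#' @param min_class_n minimum genotype-class size for the ANOVA (default 3).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `marker_calls`, one row per candidate:
#'   identifiers, class summary, `F`, `p`, `p_adj`, `growth_related`,
#'   `superior_genotype`, `population_unique`, `unique_population`.
#'   Per-SNP details (class stats, LSD matrices, frequency tables) are in
#'   attribute `details`.
#' @export
call_markers <- function(table, candidates, weights,
                         populations = table$populations,
                         alpha = 0.05, min_class_n = 3L,
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(weights) == n_individuals(table), !is.null(populations))
  miss <- setdiff(candidates, table$loci$id)
  if (length(miss) > 0L) {
    stop("candidate SNP(s) not in table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  loci <- table$loci
  details <- list()
  if (length(candidates) == 0L) {
    calls <- data.frame(
      snp = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), n_classes = integer(0),
      class_means = character(0), class_n = character(0),
      F = numeric(0), p = numeric(0), status = character(0),
      p_adj = numeric(0), growth_related = logical(0),
      superior_genotype = character(0), population_unique = logical(0),
      unique_population = character(0), stringsAsFactors = FALSE
    )
    attr(calls, "details") <- details
    attr(calls, "alpha") <- alpha
    class(calls) <- c("marker_calls", "data.frame")
    return(calls)
  }
  rows <- lapply(candidates, function(s) {
    j <- match(s, loci$id)
    d <- table$dosage[, j]
    labels <- genotype_class_labels(loci$ref[j], loci$alt[j])
    cls <- unname(labels[as.character(d)])
    test <- anova_lsd(weights, cls, min_class_n = min_class_n)
    freqs <- genotype_freqs_by_population(d, populations,
                                          loci$ref[j], loci$alt[j])
    details[[s]] <<- list(test = test, freqs = freqs)
    data.frame(
      snp = s, chrom = loci$chrom[j], pos = loci$pos[j],
      ref = loci$ref[j], alt = loci$alt[j],
      n_classes = nrow(test$class_stats),
      class_means = paste(sprintf("%s=%.4g", test$class_stats$class,
                                  test$class_stats$mean), collapse = ";"),
      class_n = paste(sprintf("%s=%d", test$class_stats$class,
                              test$class_stats$n), collapse = ";"),
      F = test$F, p = test$p,
      status = test$status,
      stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, rows)
  calls$p_adj <- calls$p
  if (p_adjust == "BH") {
    calls$p_adj[!is.na(calls$p)] <- stats::p.adjust(calls$p[!is.na(calls$p)],
                                                    method = "BH")
  }
  calls$growth_related <- !is.na(calls$p_adj) & calls$p_adj < alpha
  sup <- character(nrow(calls)); uniq <- logical(nrow(calls))
  upop <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    s <- calls$snp[i]
    gate_p <- if (p_adjust == "BH") calls$p_adj[i] else details[[s]]$test$p
    test <- details[[s]]$test
    test$p <- gate_p
    sgt <- call_superior_genotype(test, alpha = alpha)
    sup[i] <- as.character(sgt)
    if (!is.na(sgt)) {
      cl <- classify_population_unique(details[[s]]$freqs$counts, sgt)
      uniq[i] <- cl$unique
      upop[i] <- cl$population
    }
  }
  calls$superior_genotype <- sup
  calls$population_unique <- uniq
  calls$unique_population <- upop
  chrom_num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", calls$chrom)))
  ord <- order(is.na(chrom_num), chrom_num, calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "details") <- details
  attr(calls, "alpha") <- alpha
  class(calls) <- c("marker_calls", "data.frame")
  calls
}

#' Write marker-call reports
#'
#' Emits three TSVs in `dir`: all candidates, the growth-related subset and
#' the population-unique subset, each deterministically ordered by
#' chromosome then position (empty-bodied files keep their headers).
#'
#' @param calls a `marker_calls` data.frame from [call_markers()].
#' @param dir output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
report_markers <- function(calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(
    candidates = file.path(dir, "candidate_markers.tsv"),
    growth_related = file.path(dir, "growth_related_markers.tsv"),
    population_unique = file.path(dir, "population_unique_markers.tsv")
  )
  df <- as.data.frame(calls)
  utils::write.table(df, out$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(df[df$growth_related, , drop = FALSE],
                     out$growth_related, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(df[df$population_unique, , drop = FALSE],
                     out$population_unique, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
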