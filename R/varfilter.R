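#' QC filter thresholds
#'
#' Defaults reproduce the stringent post-calling filter: minor allele
#' frequency strictly greater than 0.1, per-locus sample missing rate
#' strictly below 10%, and Hardy-Weinberg exact-test p strictly greater than
#' 1e-6.
#'
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param max_missing maximum per-locus missing rate (exclusive).
#' @param hwe_p_min minimum HWE exact-test p-value (exclusive).
#' @param hwe_mode `"pooled"` tests HWE on all samples together (the
#'   combined-call-set convention; sensitive to population structure via the
#'   Wahlund effect, so strongly differentiated loci are removed).
#'   `"within"` tests each population separately and uses the smallest
#'   p-value, retaining loci that conform to HWE inside every population
#'   regardless of between-population differentiation.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(maf_min = 0.1, max_missing = 0.10, hwe_p_min = 1e-6,
                          hwe_mode = c("pooled", "within")) {
  hwe_mode <- match.arg(hwe_mode)
  stopifnot(maf_min > 0, maf_min < 1,
            max_missing > 0, max_missing < 1,
            hwe_p_min > 0, hwe_p_min < 1)
  structure(list(maf_min = maf_min, max_missing = max_missing,
                 hwe_p_min = hwe_p_min, hwe_mode = hwe_mode),
            class = "filter_config")
}

#' Minor allele frequency of one locus
#'
#' Alternate-allele frequency is `(n_het + 2 n_hom_alt) / (2 n_non_missing)`;
#' MAF folds it to `min(f, 1 - f)`. Missing genotypes are excluded.
#'
#' @param dosages numeric vector of dosages (0/1/2/NA) at one locus.
#' @return list with `alt_freq` and `maf`.
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("MAF undefined: all genotypes missing at locus")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  list(alt_freq = f, maf = min(f, 1 - f))
}

# vectorized per-locus alt frequency / MAF / missing rate over a dosage matrix
locus_qc_stats <- function(dosage) {
  n_ok <- colSums(!is.na(dosage))
  alt <- colSums(dosage, na.rm = TRUE) / (2 * n_ok)
  data.frame(
    n_nonmissing = n_ok,
    alt_freq = alt,
    maf = pmin(alt, 1 - alt),
    missing_rate = colSums(is.na(dosage)) / nrow(dosage)
  )
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum of the conditional probabilities of all heterozygote
#' counts whose probability does not exceed that of the observed count
#' (the convention of the standard SNP exact-test implementation).
#' Probabilities are computed by the stable mode-anchored recurrence; ties in
#' the conditional distribution are detected with a relative tolerance of
#' 1e-9 so mathematically equal configurations are always included together.
#' Monomorphic loci return p = 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return The exact-test p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1L) stop("HWE test requires at least one individual")
  rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (rare == 0L) return(1)
  probs <- hwe_het_probs(n, rare)
  obs <- n_het
  # heterozygote counts share the parity of the rare-allele count
  idx_obs <- (obs - rare %% 2L) / 2L + 1L
  if (idx_obs < 1L || idx_obs > length(probs) || (obs %% 2L) != (rare %% 2L)) {
    stop("impossible heterozygote count given allele counts")
  }
  p <- sum(probs[probs <= probs[idx_obs] * (1 + 1e-9)])
  min(p, 1)
}

# Conditional distribution of the heterozygote count given n individuals and
# `rare` copies of the rarer allele, via the recurrence
#   P(h - 2) / P(h) = h (h - 1) / (4 (homr + 1)(homc + 1))
# anchored at the modal count and normalized.
hwe_het_probs <- function(n, rare) {
  common <- 2L * n - rare
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  mid <- floor(rare * common / (2 * n))
  if ((mid %% 2L) != (rare %% 2L)) mid <- mid + 1L
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  if (i_mid > 1L) {
    for (i in seq(i_mid, 2L)) {
      h <- hets[i]
      homr <- (rare - h) / 2
      homc <- (common - h) / 2
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (homr + 1) * (homc + 1))
    }
  }
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1L)) {
      h <- hets[i]
      homr <- (rare - h) / 2
      homc <- (common - h) / 2
      probs[i + 1L] <- probs[i] * 4 * homr * homc / ((h + 2) * (h + 1))
    }
  }
  probs / sum(probs)
}

#' Apply MAF / missingness / HWE filters to a VariantTable
#'
#' Retains exactly the loci with `MAF > maf_min`, missing rate
#' `< max_missing` and HWE exact p `> hwe_p_min` (strict inequalities). The
#' audit log records every locus with its statistics and, for dropped loci,
#' the rule(s) it failed; the retained set does not depend on rule order.
#'
#' @param table a `variant_table`.
#' @param config a [filter_config()].
#' @return list with `table` (filtered `variant_table`) and `audit`
#'   (data.frame: `id`, `maf`, `missing_rate`, `hwe_p`, `retained`,
#'   `reasons`).
#' @export
apply_filters <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "variant_table"), inherits(config, "filter_config"))
  dos <- table$dosage
  qc <- locus_qc_stats(dos)
  hwe_locus <- function(rows) {
    vapply(seq_len(ncol(dos)), function(j) {
      d <- dos[rows, j]
      d <- d[!is.na(d)]
      if (length(d) == 0L) return(NA_real_)
      hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2))
    }, numeric(1L))
  }
  if (identical(config$hwe_mode, "within")) {
    if (is.null(table$populations)) {
      stop("hwe_mode = 'within' requires population labels in the table")
    }
    per_pop <- vapply(unique(table$populations), function(pk) {
      hwe_locus(which(table$populations == pk))
    }, numeric(ncol(dos)))
    hwe_p <- apply(per_pop, 1L, function(p) {
      if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
    })
  } else {
    hwe_p <- hwe_locus(seq_len(nrow(dos)))
  }
  pass_maf <- !is.na(qc$maf) & qc$maf > config$maf_min
  pass_miss <- qc$missing_rate < config$max_missing
  pass_hwe <- !is.na(hwe_p) & hwe_p > config$hwe_p_min
  keep <- pass_maf & pass_miss & pass_hwe
  reasons <- character(nrow(qc))
  for (j in which(!keep)) {
    r <- c(if (!pass_maf[j]) "maf",
           if (!pass_miss[j]) "missing",
           if (!pass_hwe[j]) "hwe")
    reasons[j] <- paste(r, collapse = ",")
  }
  audit <- data.frame(
    id = table$loci$id,
    maf = qc$maf,
    missing_rate = qc$missing_rate,
    hwe_p = hwe_p,
    retained = keep,
    reasons = reasons,
    stringsAsFactors = FALSE
  )
  if (!any(keep)) warning("no loci pass the filters")
  filtered <- subset_variants(table, loci = which(keep))
  list(table = filtered, audit = audit)
}

#' Classify a substitution as transition or transversion
#'
#' A<->G and C<->T (purine-purine, pyrimidine-pyrimidine) are transitions;
#' the other four unordered pairs are transversions. The class label is the
#' alphabetically ordered unordered pair, e.g. `"A/G"`.
#'
#' @param ref,alt single nucleotides (vectorized).
#' @return data.frame with `class` and `type` ("transition"/"transversion").
#' @export
classify_substitution <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("non-ACGT allele at position(s) ",
                     paste(utils::head(which(!ok), 5L), collapse = ", "))
  if (any(ref == alt)) stop("ref == alt at position(s) ",
                            paste(utils::head(which(ref == alt), 5L), collapse = ", "))
  cls <- ifelse(ref < alt, paste(ref, alt, sep = "/"), paste(alt, ref, sep = "/"))
  data.frame(class = cls,
             type = ifelse(cls %in% c("A/G", "C/T"), "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Substitution-class counts of a VariantTable
#'
#' @param table a `variant_table`.
#' @return Named integer vector of counts over the six unordered classes.
#' @export
substitution_counts <- function(table) {
  cls <- classify_substitution(table$loci$ref, table$loci$alt)$class
  classes <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
  counts <- base::table(factor(cls, levels = classes))
  stats::setNames(as.integer(counts), classes)
}

#' Summarize substitution classes
#'
#' Per-class counts and percentages of the grand total, plus aggregate
#' transition/transversion percentages. Percentages are rounded to two
#' decimals; transition and transversion percentages sum to 100 up to
#' rounding.
#'
#' @param counts named numeric vector of counts for the six unordered
#'   substitution classes ("A/C", "A/G", "A/T", "C/G", "C/T", "G/T"), or a
#'   `variant_table` (counted via [substitution_counts()]).
#' @return list with `total`, `by_class` (data.frame: `class`, `count`,
#'   `percent`, `type`), `transition_percent`, `transversion_percent`.
#' @export
summarize_substitution_classes <- function(counts) {
  if (inherits(counts, "variant_table")) counts <- substitution_counts(counts)
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  classes <- c("A/C", "A/G", "A/T", "C/G", "C/T", "G/T")
  bad <- setdiff(names(counts), classes)
  if (length(bad) > 0L) stop("unknown substitution class(es): ",
                             paste(bad, collapse = ", "))
  full <- stats::setNames(numeric(length(classes)), classes)
  full[names(counts)] <- counts
  total <- sum(full)
  if (total == 0) stop("zero total substitution count")
  type <- ifelse(classes %in% c("A/G", "C/T"), "transition", "transversion")
  by_class <- data.frame(
    class = classes,
    count = as.numeric(full),
    percent = round(100 * full / total, 2),
    type = type,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  list(
    total = total,
    by_class = by_class,
    transition_percent = round(100 * sum(full[type == "transition"]) / total, 2),
    transversion_percent = round(100 * sum(full[type == "transversion"]) / total, 2)
  )
}

#' Per-chromosome locus counts
#'
#' @param table a `variant_table`.
#' @return Named integer vector (chromosome -> count), ordered by chromosome
#'   id (natural order for numeric suffixes).
#' @export
per_chromosome_counts <- function(table) {
  chroms <- table$loci$chrom
  if (length(chroms) == 0L) return(stats::setNames(integer(0), character(0)))
  counts <- base::table(chroms)
  ids <- names(counts)
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", ids)))
  ord <- order(is.na(num), num, ids)
  stats::setNames(as.integer(counts[ord]), ids[ord])
}
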