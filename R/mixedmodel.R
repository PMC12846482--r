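#' Genomic relationship matrix (VanRaden method 1)
#'
#' Missing dosages are mean-imputed per locus, dosages centered by twice the
#' observed alternate-allele frequency, and
#' `G = W W' / (2 sum p (1 - p))` over polymorphic loci. Under an
#' unstructured Hardy-Weinberg population the mean diagonal is close to 1.
#'
#' @param table a `variant_table`.
#' @return Symmetric individuals x individuals matrix.
#' @export
compute_grm <- function(table) {
  d <- table$dosage
  if (nrow(d) < 2L) stop("need at least 2 individuals")
  means <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx) > 0L) d[idx] <- means[idx[, 2L]]
  p <- means / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  if (!any(poly)) stop("all loci are monomorphic; GRM undefined")
  W <- sweep(d[, poly, drop = FALSE], 2L, 2 * p[poly])
  G <- tcrossprod(W) / (2 * sum(p[poly] * (1 - p[poly])))
  dimnames(G) <- list(rownames(table$dosage), rownames(table$dosage))
  G
}

#' Build a fixed-effect design matrix, dropping aliased columns
#'
#' Constructs `model.matrix(~ covariates)` from a phenotype table and drops
#' linearly dependent columns (detected by pivoted QR), which arise when
#' sampling covariates are confounded with population. Dropped column names
#' are reported via a message and attached as attribute `dropped`.
#'
#' @param data data.frame of covariates (e.g. a PhenotypeTable).
#' @param covariates character vector of column names to include.
#' @return Numeric design matrix with full column rank.
#' @export
build_design <- function(data, covariates = c("population", "age", "location", "season")) {
  covariates <- intersect(covariates, names(data))
  if (length(covariates) == 0L) {
    X <- matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
    return(X)
  }
  for (v in covariates) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L) {
      covariates <- setdiff(covariates, v)
    }
  }
  if (length(covariates) == 0L) {
    return(matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  X <- stats::model.matrix(stats::reformulate(covariates), data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    message("build_design: dropped aliased column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
    attr(X, "dropped") <- dropped
  }
  X
}

#' REML fit of the genomic mixed model y = Xb + Za + e
#'
#' Single-parameter REML over the variance ratio `lambda =
#' sigma2_a / sigma2_e`, profiled through the spectral decomposition of the
#' relationship matrix `G` (with `Z = I`): the rotated model has diagonal
#' covariance `sigma2_e (lambda d_i + 1)`, so each candidate ratio costs one
#' weighted least-squares solve. The profiled restricted likelihood is
#' maximized by golden-section/parabolic search over `log(lambda)` in
#' `[-15, 15]`; GLS fixed effects (BLUE) and breeding values (BLUP) are
#' evaluated at the optimum and `y = X b + a + e` holds exactly.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (full column rank; see
#'   [build_design()]).
#' @param G genomic relationship matrix.
#' @return Object of class `lmm_fit`: list with `beta`, `sigma2_a`,
#'   `sigma2_e`, `lambda`, `heritability`, `ahat`, `ehat`, `loglik`,
#'   `y`, `X`.
#' @export
fit_lmm_reml <- function(y, X, G) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])],
               collapse = ", "))
  }
  q <- ncol(X)
  eig <- eigen(G, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)

  profile <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xstar, Xstar * w)
    XtWy <- crossprod(Xstar, ystar * w)
    beta <- solve(XtWX, XtWy)
    resid <- ystar - drop(Xstar %*% beta)
    rss <- sum(w * resid^2)
    sigma2e <- rss / (n - q)
    # guard the degenerate perfect-fit case (rss -> 0) against log(0)
    sigma2e_safe <- max(sigma2e, 1e-300)
    ll <- -0.5 * ((n - q) * log(2 * pi * sigma2e_safe) + sum(log(lam * d + 1)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - q))
    list(ll = as.numeric(ll), beta = beta, resid = resid, w = w,
         sigma2e = sigma2e, lam = lam)
  }
  opt <- stats::optimize(function(x) profile(x)$ll,
                         interval = c(-15, 15), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, -15, 15)
  lls <- vapply(cand, function(x) profile(x)$ll, numeric(1L))
  best <- profile(cand[which.max(lls)])
  sigma2e <- best$sigma2e
  sigma2a <- best$lam * sigma2e
  # BLUP in the rotated basis: a* = lambda d w (y* - X* b)
  ahat <- drop(U %*% (best$lam * d * best$w * best$resid))
  fitted_fixed <- drop(X %*% best$beta)
  ehat <- y - fitted_fixed - ahat
  structure(
    list(
      beta = stats::setNames(drop(best$beta), colnames(X)),
      sigma2_a = sigma2a,
      sigma2_e = sigma2e,
      lambda = best$lam,
      heritability = sigma2a / (sigma2a + sigma2e),
      ahat = ahat,
      ehat = ehat,
      loglik = best$ll,
      y = y,
      X = X
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Genomic mixed model (REML)\n")
  cat(sprintf("  sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$sigma2_a, x$sigma2_e, x$heritability))
  cat("  fixed effects:", length(x$beta), "column(s)\n")
  invisible(x)
}

#' Adjust phenotypes using a fitted genomic mixed model
#'
#' `fixed_only` (default) returns `y - X b`: systematic population and
#' environmental effects are removed while additive genetic signal is
#' preserved for downstream association. `full_residual` returns
#' `e = y - X b - a`, the literal model residual; the BLUP term absorbs
#' additive genetic signal, so this mode attenuates marker effects and is
#' kept for fidelity to the adjustment as described.
#'
#' @param fit an `lmm_fit`.
#' @param mode `"fixed_only"` or `"full_residual"`.
#' @return Numeric vector of adjusted phenotypes with attribute
#'   `adjust_mode`.
#' @export
adjust_phenotypes <- function(fit, mode = c("fixed_only", "full_residual")) {
  mode <- match.arg(mode)
  out <- switch(mode,
                fixed_only = fit$y - drop(fit$X %*% fit$beta),
                full_residual = fit$ehat)
  attr(out, "adjust_mode") <- mode
  out
}

#' EMMAX-style mixed-linear-model GWAS
#'
#' Variance components are estimated once by REML on the null (no-marker)
#' model; every locus is then tested by GLS under the fixed covariance
#' `V = sigma2_a G + sigma2_e I` (Wald t test of the per-allele dosage
#' effect, mean-imputing missing dosages). Loci monomorphic in the tested
#' sample are skipped and logged. The Bonferroni threshold is `alpha / m`
#' with `m` the number of loci actually tested.
#'
#' @param y adjusted phenotype vector (see [adjust_phenotypes()]).
#' @param table a filtered `variant_table` with the same individuals as `y`.
#' @param G genomic relationship matrix. With `loco = TRUE` this argument is
#'   ignored and a leave-one-chromosome-out GRM is built per chromosome from
#'   `table`, so a marker's own polygenic contribution is never part of the
#'   covariance it is tested against (proximal contamination).
#' @param alpha family-wise error level for Bonferroni (default 0.05).
#' @param X fixed-effect design for the per-marker model (default intercept
#'   only, appropriate for pre-adjusted phenotypes).
#' @param loco use leave-one-chromosome-out kinship (default FALSE).
#' @return data.frame of class `gwas_result`: `snp`, `chrom`, `pos`, `ref`,
#'   `alt`, `beta`, `se`, `p`, `significant`, `method`. Attributes:
#'   `m_tested`, `threshold`, `skipped`, `fit` (the null-model `lmm_fit`;
#'   one per chromosome under LOCO).
#' @export
gwas_mlm <- function(y, table, G = NULL, alpha = 0.05, X = NULL,
                     loco = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == n_individuals(table))
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!loco && is.null(G)) stop("supply G or set loco = TRUE")
  dos <- table$dosage
  means <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx) > 0L) dos[idx] <- means[idx[, 2L]]
  vars <- apply(dos, 2L, stats::var)
  tested <- vars > 0
  skipped <- table$loci$id[!tested]
  if (length(skipped) > 0L) {
    message("gwas_mlm: skipped ", length(skipped),
            " locus/loci monomorphic in the tested sample")
  }
  m <- sum(tested)
  threshold <- alpha / m

  # GLS Wald tests of a block of markers under a fixed kinship
  test_block <- function(Gk, cols) {
    fit <- fit_lmm_reml(y, X, Gk)
    eig <- eigen(Gk, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    U <- eig$vectors
    sw <- sqrt(1 / (fit$lambda * d + 1))
    yt <- drop(crossprod(U, y)) * sw
    Xt <- crossprod(U, X) * sw
    Gt <- crossprod(U, dos[, cols, drop = FALSE]) * sw
    # Frisch-Waugh: residualize phenotype and markers on the rotated fixed
    # effects, then per-marker simple regression
    XtX <- crossprod(Xt)
    Px <- function(M) M - Xt %*% solve(XtX, crossprod(Xt, M))
    My <- drop(Px(matrix(yt, ncol = 1L)))
    MG <- Px(Gt)
    sxx <- colSums(MG^2)
    sxy <- colSums(MG * My)
    beta <- sxy / sxx
    df <- n - ncol(X) - 1L
    rss <- sum(My^2) - beta^2 * sxx
    rss[rss < 0] <- 0
    se <- sqrt(rss / df / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    p[p == 0] <- .Machine$double.xmin
    list(beta = beta, se = se, p = p, fit = fit)
  }

  if (loco) {
    chroms <- unique(table$loci$chrom)
    if (length(chroms) < 2L) {
      stop("LOCO requires at least two chromosomes")
    }
    blocks <- lapply(chroms, function(ch) {
      on_ch <- table$loci$chrom == ch
      cols <- which(tested & on_ch)
      if (length(cols) == 0L) return(NULL)
      G_loco <- compute_grm(subset_variants(table, loci = which(!on_ch)))
      c(test_block(G_loco, cols), list(cols = cols))
    })
    blocks <- Filter(Negate(is.null), blocks)
    ord <- order(unlist(lapply(blocks, `[[`, "cols")))
    beta <- unlist(lapply(blocks, `[[`, "beta"))[ord]
    se <- unlist(lapply(blocks, `[[`, "se"))[ord]
    p <- unlist(lapply(blocks, `[[`, "p"))[ord]
    fit <- lapply(blocks, `[[`, "fit")
    tested_idx <- sort(unlist(lapply(blocks, `[[`, "cols")))
  } else {
    blk <- test_block(G, which(tested))
    beta <- blk$beta; se <- blk$se; p <- blk$p; fit <- blk$fit
    tested_idx <- which(tested)
  }

  res <- data.frame(
    snp = table$loci$id[tested_idx],
    chrom = table$loci$chrom[tested_idx],
    pos = table$loci$pos[tested_idx],
    ref = table$loci$ref[tested_idx],
    alt = table$loci$alt[tested_idx],
    beta = unname(beta),
    se = unname(se),
    p = unname(p),
    significant = unname(p) < threshold,
    method = "MLM",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(res, "m_tested") <- m
  attr(res, "threshold") <- threshold
  attr(res, "skipped") <- skipped
  attr(res, "fit") <- fit
  class(res) <- c("gwas_result", "data.frame")
  res
}

#' Merge significant-locus lists from multiple GWAS models
#'
#' Takes per-model significant-SNP tables (e.g. from MLM plus externally
#' computed FarmCPU/BLINK runs), unions them by canonical locus identifier
#' `chrom_pos_ref_alt`, concatenates the contributing method labels
#' (alphabetically, comma-separated) and sorts by chromosome then position.
#' The operation is commutative and idempotent over its inputs.
#'
#' @param ... data.frames each with columns `snp` and `method` (a
#'   `gwas_result` works directly; lists of data.frames are flattened).
#' @return data.frame with columns `SNP`, `CHR`, `POS`, `REF`, `ALT`,
#'   `Method`.
#' @export
merge_model_results <- function(...) {
  inputs <- list(...)
  flat <- list()
  for (x in inputs) {
    if (is.data.frame(x)) flat <- c(flat, list(x)) else flat <- c(flat, x)
  }
  rows <- lapply(flat, function(df) {
    stopifnot(is.data.frame(df))
    if (!all(c("snp", "method") %in% names(df))) {
      stop("each result table needs 'snp' and 'method' columns")
    }
    df[, c("snp", "method")]
  })
  all_rows <- do.call(rbind, rows)
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    return(data.frame(SNP = character(0), CHR = character(0),
                      POS = integer(0), REF = character(0),
                      ALT = character(0), Method = character(0),
                      stringsAsFactors = FALSE))
  }
  parsed <- parse_locus_ids(all_rows$snp)
  methods <- vapply(split(all_rows$method, all_rows$snp), function(m) {
    paste(sort(unique(m)), collapse = ", ")
  }, character(1L))
  uniq <- parsed[!duplicated(parsed$id), , drop = FALSE]
  chrom_num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", uniq$chrom)))
  ord <- order(is.na(chrom_num), chrom_num, uniq$chrom, uniq$pos)
  uniq <- uniq[ord, , drop = FALSE]
  data.frame(
    SNP = uniq$id,
    CHR = uniq$chrom,
    POS = uniq$pos,
    REF = uniq$ref,
    ALT = uniq$alt,
    Method = unname(methods[uniq$id]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
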