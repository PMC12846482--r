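#' Per-population genetic diversity statistics
#'
#' For each population and locus, with within-population alternate-allele
#' frequency `p`, `q = 1 - p`, `m` non-missing alleles and `j` alternate
#' alleles:
#' observed heterozygosity `Ho` is the heterozygote fraction among
#' non-missing genotypes; expected heterozygosity `He = 2pq`; nucleotide
#' diversity `Pi = 2 j (m - j) / (m (m - 1))` (the unbiased per-site
#' pairwise-difference estimator); polymorphism information content
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`. The report gives the mean of each
#' statistic over loci; monomorphic-within-population loci contribute zero
#' unless `polymorphic_only = TRUE` excludes them.
#'
#' @param table a `variant_table`.
#' @param populations population labels (defaults to `table$populations`).
#' @param polymorphic_only if TRUE, average only over loci polymorphic
#'   within the population.
#' @return data.frame with one row per population: `population`, `n`,
#'   `n_loci`, `Ho`, `He`, `Pi`, `PIC`.
#' @export
diversity_stats <- function(table, populations = table$populations,
                            polymorphic_only = FALSE) {
  stopifnot(inherits(table, "variant_table"), !is.null(populations))
  pops <- unique(populations)
  out <- lapply(pops, function(pk) {
    rows <- which(populations == pk)
    if (length(rows) < 2L) {
      stop("population ", pk, " has fewer than 2 individuals")
    }
    d <- table$dosage[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(d))
    m <- 2 * n_ok
    j <- colSums(d, na.rm = TRUE)
    usable <- m >= 2
    p <- ifelse(usable, j / m, NA_real_)
    q <- 1 - p
    ho <- ifelse(usable, colSums(d == 1, na.rm = TRUE) / n_ok, NA_real_)
    he <- 2 * p * q
    pi <- ifelse(usable, 2 * j * (m - j) / (m * (m - 1)), NA_real_)
    pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
    sel <- usable
    if (polymorphic_only) sel <- sel & !is.na(p) & p > 0 & p < 1
    data.frame(
      population = pk, n = length(rows), n_loci = sum(sel),
      Ho = mean(ho[sel]), He = mean(he[sel]),
      Pi = mean(pi[sel]), PIC = mean(pic[sel]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Pairwise allele-sharing (identity-by-state) distance
#'
#' `d(i, j) = sum |dosage_i - dosage_j| / (2 L_ij)` over the `L_ij`
#' pairwise-complete loci: the proportion of allele differences between two
#' individuals (1 - IBS). Identical genotypes give 0; opposite homozygotes
#' at every locus give 1.
#'
#' @param table a `variant_table`.
#' @return Symmetric numeric matrix with zero diagonal; row/col names are
#'   individual ids.
#' @export
ibs_distance <- function(table) {
  d <- table$dosage
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 individuals")
  M <- !is.na(d)
  A0 <- (d == 0) & M; A1 <- (d == 1) & M; A2 <- (d == 2) & M
  A0[is.na(A0)] <- FALSE; A1[is.na(A1)] <- FALSE; A2[is.na(A2)] <- FALSE
  storage.mode(A0) <- "double"
  storage.mode(A1) <- "double"
  storage.mode(A2) <- "double"
  storage.mode(M) <- "double"
  L <- tcrossprod(M)
  diffs <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1) +
    2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  off <- L == 0 & row(L) != col(L)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop("no shared non-missing loci for pair ",
         rownames(d)[idx[1L]], " / ", rownames(d)[idx[2L]])
  }
  Ld <- L
  diag(Ld) <- 1  # avoid 0/0 on the diagonal; distance there is 0 anyway
  dist_mat <- diffs / (2 * Ld)
  diag(dist_mat) <- 0
  dimnames(dist_mat) <- list(rownames(d), rownames(d))
  dist_mat
}

#' Nei's standard genetic distance between populations
#'
#' Population-level distance `D = -ln I`, where the normalized identity
#' `I = sum(p1 p2 + q1 q2) / sqrt(sum(p1^2 + q1^2) sum(p2^2 + q2^2))` is
#' accumulated over loci using within-population allele frequencies.
#'
#' @param table a `variant_table`.
#' @param populations population labels (defaults to `table$populations`).
#' @return Symmetric matrix of distances between populations.
#' @export
nei_distance <- function(table, populations = table$populations) {
  pops <- unique(populations)
  freqs <- vapply(pops, function(pk) {
    d <- table$dosage[populations == pk, , drop = FALSE]
    colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  }, numeric(n_loci(table)))
  k <- length(pops)
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      p1 <- freqs[, i]; p2 <- freqs[, j]
      ok <- !is.na(p1) & !is.na(p2)
      p1 <- p1[ok]; p2 <- p2[ok]
      jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
      jx <- sum(p1^2 + (1 - p1)^2)
      jy <- sum(p2^2 + (1 - p2)^2)
      D[i, j] <- D[j, i] <- -log(jxy / sqrt(jx * jy))
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` is joined (ties broken by the
#' lowest index pair, so output is deterministic), with the standard
#' branch-length formulas. Negative branch lengths are clamped to zero and
#' the deficit transferred to the sibling edge, preserving the pair's path
#' length.
#'
#' @param distances symmetric numeric matrix with zero diagonal.
#' @param labels taxon labels (defaults to row names).
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighbor_joining <- function(distances, labels = rownames(distances)) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  sub <- labels  # Newick strings for the current clusters
  active <- seq_len(n)
  while (length(active) > 3L) {
    r <- length(active)
    Dc <- D[active, active, drop = FALSE]
    R <- rowSums(Dc)
    Q <- (r - 2) * Dc - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # lowest-index pair among ties (row-major over i < j)
    hit <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    dij <- Dc[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    ai <- active[i]; aj <- active[j]
    new_d <- (D[ai, active] + D[aj, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    k <- nrow(D)
    D[k, active] <- new_d
    D[active, k] <- new_d
    D[k, k] <- 0
    sub <- c(sub, sprintf("(%s:%.12g,%s:%.12g)", sub[ai], li, sub[aj], lj))
    active <- c(setdiff(active, c(ai, aj)), k)
  }
  a <- active[1L]; b <- active[2L]; c_ <- active[3L]
  la <- max((D[a, b] + D[a, c_] - D[b, c_]) / 2, 0)
  lb <- max((D[a, b] + D[b, c_] - D[a, c_]) / 2, 0)
  lc <- max((D[a, c_] + D[b, c_] - D[a, b]) / 2, 0)
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    sub[a], la, sub[b], lb, sub[c_], lc)
  ape::read.tree(text = newick)
}
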