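#' Genes overlapping a window around each SNP
#'
#' A gene is reported for a SNP when its `[start, end]` interval intersects
#' the closed interval `[pos - window, pos + window]` (1-based, inclusive;
#' strand ignored). SNPs on chromosomes absent from the annotation get no
#' genes (logged, not an error).
#'
#' @param snps data.frame with `chrom`, `pos` and (optionally) `id`
#'   columns, e.g. from [parse_locus_ids()].
#' @param genes gene models data.frame (see [read_gene_models()]).
#' @param window half-width of the window in bp (default 50000).
#' @return data.frame with `snp_id`, `gene_id`.
#' @export
genes_near_snp <- function(snps, genes, window = 50000L) {
  stopifnot(window >= 0)
  if (is.null(snps$id)) snps$id <- paste(snps$chrom, snps$pos, sep = "_")
  off_chrom <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(off_chrom) > 0L) {
    message("genes_near_snp: no annotation for chromosome(s): ",
            paste(off_chrom, collapse = ", "))
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, snps$pos - window),
                              end = snps$pos + window)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, gene_gr))
  data.frame(
    snp_id = snps$id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' SNPs located inside gene bodies
#'
#' Reports every SNP with `gene.start <= pos <= gene.end` (1-based
#' inclusive); a SNP inside several overlapping genes is reported under each.
#'
#' @param table a `variant_table`.
#' @param genes gene models data.frame.
#' @return data.frame with `gene_id`, `snp_id`.
#' @export
snps_in_genes <- function(table, genes) {
  snp_gr <- GenomicRanges::GRanges(
    seqnames = table$loci$chrom,
    ranges = IRanges::IRanges(start = table$loci$pos, width = 1L)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, snp_gr))
  data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    snp_id = table$loci$id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
}

#' Composite linkage-disequilibrium r-squared between two loci
#'
#' Squared Pearson correlation of allele dosages over pairwise-complete
#' individuals (genotypic/composite LD; no phasing required).
#'
#' @param dosages_a,dosages_b numeric dosage vectors (0/1/2/NA).
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2L) stop("fewer than 2 pairwise-complete individuals")
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("LD undefined: zero dosage variance at one of the loci")
  }
  stats::cor(a, b)^2
}

#' Expand significant tag SNPs to linked loci within their gene pools
#'
#' Each tag SNP is annotated to genes within `window` bp; all SNPs inside
#' those genes (same chromosome) form the tag's pool, and pool members with
#' dosage r-squared strictly greater than `r2_min` against the tag are
#' flagged linked. Tags without gene annotation are excluded from expansion
#' and reported. The combined candidate list is the union of annotated tags
#' and newly linked SNPs, deduplicated; a SNP linked to several tags keeps
#' the tag with the highest r-squared.
#'
#' @param tags character vector of tag SNP ids (must exist in `table`).
#' @param table a filtered `variant_table`.
#' @param genes gene models data.frame.
#' @param window annotation half-window in bp (default 50000).
#' @param r2_min LD threshold (default 0.5, exclusive).
#' @param pooled if TRUE, every tag is compared against the union of all
#'   annotated genes' SNPs (same chromosome only) instead of its own genes'.
#' @param ld_samples optional selector (indices, logical mask or individual
#'   ids) restricting the individuals used for the r-squared computation,
#'   e.g. one population; by default all samples are pooled, which inflates
#'   LD in structured data.
#' @return list with `sets` (per-tag data.frame: `tag`, `snp`, `r2`,
#'   `linked`), `combined` (data.frame: `snp`, `chrom`, `pos`, `source`
#'   ("tag"/"linked"), `best_tag`, `r2`), `tag_genes` (tag -> gene table) and
#'   `unannotated_tags`.
#' @export
expand_tags <- function(tags, table, genes, window = 50000L, r2_min = 0.5,
                        pooled = FALSE, ld_samples = NULL) {
  tags <- unique(tags)
  dosage <- table$dosage
  if (!is.null(ld_samples)) dosage <- dosage[ld_samples, , drop = FALSE]
  miss <- setdiff(tags, table$loci$id)
  if (length(miss) > 0L) {
    stop("tag SNP(s) not present in the variant table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  tag_info <- parse_locus_ids(tags)
  tag_genes <- genes_near_snp(
    data.frame(chrom = tag_info$chrom, pos = tag_info$pos, id = tag_info$id,
               stringsAsFactors = FALSE),
    genes, window = window
  )
  annotated <- intersect(tags, unique(tag_genes$snp_id))
  unannotated <- setdiff(tags, annotated)
  if (length(unannotated) > 0L) {
    message("expand_tags: excluded ", length(unannotated),
            " tag(s) without gene annotation: ",
            paste(unannotated, collapse = ", "))
  }
  gene_snps <- snps_in_genes(table, genes)
  loci <- table$loci
  sets <- list()
  for (tg in annotated) {
    tg_chrom <- loci$chrom[match(tg, loci$id)]
    pool_genes <- if (pooled) unique(tag_genes$gene_id) else
      tag_genes$gene_id[tag_genes$snp_id == tg]
    pool <- unique(gene_snps$snp_id[gene_snps$gene_id %in% pool_genes])
    pool <- pool[loci$chrom[match(pool, loci$id)] == tg_chrom]
    # the tag belongs to its own set (r2 = 1) even when it falls outside the
    # gene bodies it is annotated to by the window
    pool <- union(tg, pool)
    tg_dos <- dosage[, match(tg, loci$id)]
    r2 <- vapply(pool, function(s) {
      tryCatch(ld_r2(tg_dos, dosage[, match(s, loci$id)]),
               error = function(e) NA_real_)
    }, numeric(1L))
    sets[[tg]] <- data.frame(
      tag = tg, snp = pool, r2 = unname(r2),
      linked = !is.na(r2) & r2 > r2_min,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  sets_df <- if (length(sets) > 0L) do.call(rbind, c(sets, list(make.row.names = FALSE)))
  else data.frame(tag = character(0), snp = character(0),
                  r2 = numeric(0), linked = logical(0))
  linked_rows <- sets_df[sets_df$linked & !(sets_df$snp %in% annotated), , drop = FALSE]
  best <- if (nrow(linked_rows) > 0L) {
    linked_rows <- linked_rows[order(linked_rows$snp, -linked_rows$r2), , drop = FALSE]
    linked_rows[!duplicated(linked_rows$snp), , drop = FALSE]
  } else linked_rows
  combined <- rbind(
    if (length(annotated) > 0L) data.frame(
      snp = annotated, source = "tag", best_tag = annotated, r2 = 1,
      stringsAsFactors = FALSE
    ),
    if (nrow(best) > 0L) data.frame(
      snp = best$snp, source = "linked", best_tag = best$tag, r2 = best$r2,
      stringsAsFactors = FALSE
    )
  )
  if (is.null(combined)) {
    combined <- data.frame(snp = character(0), source = character(0),
                           best_tag = character(0), r2 = numeric(0))
  }
  if (nrow(combined) > 0L) {
    info <- parse_locus_ids(combined$snp)
    combined$chrom <- info$chrom
    combined$pos <- info$pos
    chrom_num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", combined$chrom)))
    ord <- order(is.na(chrom_num), chrom_num, combined$chrom, combined$pos)
    combined <- combined[ord, c("snp", "chrom", "pos", "source", "best_tag", "r2")]
    rownames(combined) <- NULL
  }
  list(sets = sets_df, combined = combined, tag_genes = tag_genes,
       unannotated_tags = unannotated)
}
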