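#' Construct a VariantTable
#'
#' The central genotype container: locus metadata plus an individuals-by-loci
#' allele-dosage matrix. Dosages count copies of the alternate allele
#' (0, 1, 2) with `NA` for missing genotypes.
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` (single nucleotides, A/C/G/T). Positions must be strictly
#'   increasing within each chromosome.
#' @param dosage numeric matrix, individuals x loci, entries in
#'   \{0, 1, 2, NA\}. Row names are individual ids; column names are set to
#'   the canonical locus ids `chrom_pos_ref_alt`.
#' @param populations optional character vector of population labels, one per
#'   individual.
#' @return An object of class `variant_table`: a list with elements `loci`
#'   (data.frame, including an `id` column), `dosage` and `populations`.
#' @export
variant_table <- function(loci, dosage, populations = NULL) {
  stopifnot(is.data.frame(loci), is.matrix(dosage))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0L) {
    stop("loci is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  loci <- as.data.frame(loci[required], stringsAsFactors = FALSE)
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  if (nrow(loci) != ncol(dosage)) {
    stop("ncol(dosage) [", ncol(dosage), "] != nrow(loci) [", nrow(loci), "]")
  }
  bad_allele <- !(loci$ref %in% c("A", "C", "G", "T")) |
    !(loci$alt %in% c("A", "C", "G", "T"))
  if (any(bad_allele)) {
    stop("non-ACGT or missing alleles at loci: ",
         paste(utils::head(which(bad_allele), 5L), collapse = ", "))
  }
  if (any(loci$ref == loci$alt)) {
    stop("ref == alt at loci: ",
         paste(utils::head(which(loci$ref == loci$alt), 5L), collapse = ", "))
  }
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0L && !all(vals %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  }
  loci$id <- locus_ids(loci)
  colnames(dosage) <- loci$id
  if (!is.null(populations)) {
    if (length(populations) != nrow(dosage)) {
      stop("populations must have one label per individual")
    }
    populations <- as.character(populations)
  }
  structure(
    list(loci = loci, dosage = dosage, populations = populations),
    class = "variant_table"
  )
}

#' Canonical locus identifiers (chrom_pos_ref_alt)
#'
#' @param loci data.frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return Character vector of identifiers.
#' @export
locus_ids <- function(loci) {
  paste(loci$chrom, loci$pos, loci$ref, loci$alt, sep = "_")
}

#' Parse canonical locus identifiers
#'
#' Inverse of [locus_ids()]. Leading "Chr"/"LG" style chromosome prefixes are
#' kept verbatim; identifiers are `chrom_pos_ref_alt`.
#'
#' @param ids character vector of identifiers.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `id`.
#' @export
parse_locus_ids <- function(ids) {
  pat <- "^(.+)_([0-9]+)_([ACGT])_([ACGT])$"
  bad <- !grepl(pat, ids)
  if (any(bad)) {
    stop("malformed locus identifier(s) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ": ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  data.frame(
    chrom = sub(pat, "\\1", ids),
    pos = as.integer(sub(pat, "\\2", ids)),
    ref = sub(pat, "\\3", ids),
    alt = sub(pat, "\\4", ids),
    id = ids,
    stringsAsFactors = FALSE
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$dosage), "individuals x", nrow(x$loci),
      "loci on", length(unique(x$loci$chrom)), "chromosome(s)\n")
  if (!is.null(x$populations)) {
    tab <- table(x$populations)
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of individuals / loci in a VariantTable
#' @param table a `variant_table`.
#' @return integer count.
#' @export
n_individuals <- function(table) nrow(table$dosage)

#' @rdname n_individuals
#' @export
n_loci <- function(table) nrow(table$loci)

#' Subset a VariantTable by individuals and/or loci
#'
#' @param table a `variant_table`.
#' @param individuals optional index/logical/character selector for rows.
#' @param loci optional index/logical/character (locus id) selector.
#' @return A `variant_table`.
#' @export
subset_variants <- function(table, individuals = NULL, loci = NULL) {
  dos <- table$dosage
  pops <- table$populations
  ldf <- table$loci
  if (!is.null(individuals)) {
    dos <- dos[individuals, , drop = FALSE]
    if (!is.null(pops)) {
      names(pops) <- rownames(table$dosage)
      pops <- if (is.character(individuals)) pops[individuals] else pops[individuals]
      pops <- unname(pops)
    }
  }
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, ldf$id)
    dos <- dos[, loci, drop = FALSE]
    ldf <- ldf[loci, , drop = FALSE]
  }
  variant_table(ldf, dos, populations = pops)
}

#' Read a multi-sample VCF into a VariantTable
#'
#' Only biallelic SNPs are kept: indels and multiallelic records are dropped
#' at read time and their count reported. Genotypes are taken from the GT
#' field; phased (`|`) and unphased (`/`) separators are treated identically,
#' and `./.` (or `.`) becomes `NA`.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped/gzipped).
#' @param populations optional named character vector (names = sample ids) or
#'   unnamed vector in sample order, giving population labels.
#' @return A `variant_table`. The number of excluded records is attached as
#'   attribute `n_excluded`.
#' @export
read_vcf <- function(path, populations = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  snp <- vcfR::is.biallelic(vcf) &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  snp[is.na(snp)] <- FALSE
  n_excluded <- sum(!snp)
  if (n_excluded > 0L) {
    message("read_vcf: dropped ", n_excluded,
            " non-biallelic/non-SNP record(s)")
  }
  vcf <- vcf[snp, ]
  fix <- fix[snp, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- t(matrix(code[gt], nrow = nrow(gt), ncol = ncol(gt)))
  rownames(dos) <- colnames(gt)
  tab <- variant_table(
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
               ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    dos,
    populations = match_populations(populations, rownames(dos))
  )
  attr(tab, "n_excluded") <- n_excluded
  tab
}

match_populations <- function(populations, sample_ids) {
  if (is.null(populations)) return(NULL)
  if (!is.null(names(populations))) {
    miss <- setdiff(sample_ids, names(populations))
    if (length(miss) > 0L) {
      stop("no population label for sample(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    populations <- populations[sample_ids]
  }
  unname(as.character(populations))
}

#' Write a VariantTable to VCF
#'
#' Emits a VCF 4.2 file with GT-only genotype fields (`./.` for missing).
#' Output is gzip-compressed; a `.gz` suffix is appended when absent.
#'
#' @param table a `variant_table`.
#' @param path output path (`.vcf.gz`).
#' @return The path written, invisibly.
#' @export
write_vcf <- function(table, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  loci <- table$loci
  fix <- cbind(
    CHROM = loci$chrom, POS = as.character(loci$pos), ID = loci$id,
    REF = loci$ref, ALT = loci$alt, QUAL = ".", FILTER = "PASS", INFO = "."
  )
  code <- c("0/0", "0/1", "1/1")
  gt_chr <- matrix("./.", nrow = nrow(loci), ncol = nrow(table$dosage))
  d <- t(table$dosage)
  ok <- !is.na(d)
  gt_chr[ok] <- code[d[ok] + 1L]
  gt <- cbind(FORMAT = "GT", gt_chr)
  colnames(gt) <- c("FORMAT", rownames(table$dosage))
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(loci$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Uses `type == "gene"` features only; mRNA/exon substructure is ignored.
#' Coordinates are 1-based inclusive (GFF convention).
#'
#' @param path path to a GFF3 file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || all(is.na(ids))) ids <- gr$Name
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
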