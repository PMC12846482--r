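test_that("gene-window overlap respects closed-interval boundaries", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "Chr1",
                      start = c(149000L, 150001L), end = c(160000L, 160000L),
                      strand = "+", stringsAsFactors = FALSE)
  snp <- data.frame(chrom = "Chr1", pos = 100000L, id = "s1")
  hits <- genes_near_snp(snp, genes, window = 50000L)
  expect_equal(hits$gene_id, "g1")  # 149000 <= 150000; 150001 is out

  # chromosome missing from the annotation: empty, with a log message
  snp2 <- data.frame(chrom = "Chr9", pos = 1000L, id = "s2")
  expect_message(h2 <- genes_near_snp(snp2, genes), "no annotation")
  expect_equal(nrow(h2), 0L)
})

test_that("gene-window overlap matches a brute-force interval scan", {
  set.seed(61)
  genes <- data.frame(
    gene_id = paste0("g", 1:200),
    chrom = sample(paste0("Chr", 1:3), 200, replace = TRUE),
    start = sample(1:900000, 200),
    strand = "+", stringsAsFactors = FALSE
  )
  genes$end <- genes$start + sample(1000:40000, 200)
  snps <- data.frame(
    chrom = sample(paste0("Chr", 1:3), 50, replace = TRUE),
    pos = sample(1:900000, 50),
    id = paste0("s", 1:50), stringsAsFactors = FALSE
  )
  w <- 50000L
  hits <- genes_near_snp(snps, genes, window = w)
  got <- sort(paste(hits$snp_id, hits$gene_id))
  want <- character(0)
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes))) {
      if (snps$chrom[i] == genes$chrom[j] &&
          genes$end[j] >= snps$pos[i] - w && genes$start[j] <= snps$pos[i] + w) {
        want <- c(want, paste(snps$id[i], genes$gene_id[j]))
      }
    }
  }
  expect_equal(got, sort(want))
})

test_that("SNP-in-gene membership is inclusive and handles nesting", {
  genes <- data.frame(gene_id = c("outer", "inner"), chrom = "Chr1",
                      start = c(10000L, 12000L), end = c(20000L, 15000L),
                      strand = "+", stringsAsFactors = FALSE)
  dos <- matrix(rbinom(3 * 4, 2, 0.5), nrow = 3)
  loci <- data.frame(chrom = "Chr1", pos = c(10000L, 13000L, 20000L, 21000L),
                     ref = "A", alt = "G")
  tab <- variant_table(loci, dos)
  hits <- snps_in_genes(tab, genes)
  in_outer <- hits$snp_id[hits$gene_id == "outer"]
  expect_equal(length(in_outer), 3L)  # both bounds inclusive, 21000 out
  expect_equal(hits$snp_id[hits$gene_id == "inner"], tab$loci$id[2])
})

test_that("dosage r-squared equals the from-scratch covariance oracle", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)  # perfect negative

  set.seed(62)
  for (i in 1:25) {
    a <- rbinom(50, 2, runif(1, 0.2, 0.8))
    b <- rbinom(50, 2, runif(1, 0.2, 0.8))
    if (var(a) == 0 || var(b) == 0) next
    oracle <- (mean(a * b) - mean(a) * mean(b))^2 /
      (mean(a^2) - mean(a)^2) / (mean(b^2) - mean(b)^2)
    expect_equal(ld_r2(a, b), oracle, tolerance = 1e-12)
    expect_identical(ld_r2(a, b), ld_r2(b, a))
  }

  # pairwise-complete handling and degenerate input
  a <- c(0, 1, 2, NA, 2)
  b <- c(0, 1, NA, 2, 2)
  expect_equal(ld_r2(a, b), cor(a[c(1, 2, 5)], b[c(1, 2, 5)])^2)
  expect_error(ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero dosage variance")
  expect_error(ld_r2(c(0, NA, NA), c(NA, 1, 2)), "pairwise-complete")
})

test_that("tag expansion links, dedups and reports unannotated tags", {
  # hand-built table: tag t with a perfect partner, a sub-threshold locus,
  # and a second tag on another chromosome without gene annotation
  set.seed(63)
  base <- rbinom(60, 2, 0.5)
  noisy <- base
  noisy[sample(60, 25)] <- rbinom(25, 2, 0.5)
  other <- rbinom(60, 2, 0.5)
  dos <- cbind(base, base, noisy, other)
  loci <- data.frame(chrom = c("Chr1", "Chr1", "Chr1", "Chr2"),
                     pos = c(1000L, 2000L, 3000L, 1000L),
                     ref = "A", alt = "G")
  tab <- variant_table(loci, dos)
  genes <- data.frame(gene_id = "g1", chrom = "Chr1", start = 500L,
                      end = 5000L, strand = "+", stringsAsFactors = FALSE)
  tags <- tab$loci$id[c(1, 4)]
  expect_message(
    res <- expand_tags(tags, tab, genes, window = 1000L, r2_min = 0.5),
    "without gene annotation"
  )
  expect_equal(res$unannotated_tags, tab$loci$id[4])
  # tag is in its own set at r2 = 1
  own <- res$sets[res$sets$tag == tags[1] & res$sets$snp == tags[1], ]
  expect_equal(own$r2, 1)
  # perfect partner linked; combined = annotated tag + linked partner(s)
  expect_true(tab$loci$id[2] %in% res$combined$snp[res$combined$source == "linked"])
  expect_equal(nrow(res$combined),
               1L + sum(res$sets$linked & !(res$sets$snp %in% tags)))

  # raising the threshold shrinks the linked set monotonically
  n_linked <- vapply(c(0.2, 0.5, 0.8, 0.95), function(r2) {
    r <- suppressMessages(expand_tags(tags, tab, genes, window = 1000L,
                                      r2_min = r2))
    sum(r$combined$source == "linked")
  }, numeric(1L))
  expect_true(all(diff(n_linked) <= 0))
})

test_that("a SNP linked to two tags keeps the best tag only once", {
  set.seed(64)
  t1 <- rbinom(80, 2, 0.5)
  partner <- t1
  partner[sample(80, 8)] <- rbinom(8, 2, 0.5)
  t2 <- partner
  t2[sample(80, 20)] <- rbinom(20, 2, 0.5)
  dos <- cbind(t1, partner, t2)
  loci <- data.frame(chrom = "Chr1", pos = c(1000L, 2000L, 3000L),
                     ref = "A", alt = "G")
  tab <- variant_table(loci, dos)
  genes <- data.frame(gene_id = "g1", chrom = "Chr1", start = 1L,
                      end = 10000L, strand = "+", stringsAsFactors = FALSE)
  tags <- tab$loci$id[c(1, 3)]
  res <- expand_tags(tags, tab, genes, window = 1000L, r2_min = 0.2)
  row <- res$combined[res$combined$snp == tab$loci$id[2], ]
  expect_equal(nrow(row), 1L)
  r2_t1 <- ld_r2(t1, partner)
  r2_t2 <- ld_r2(t2, partner)
  expect_equal(row$best_tag, tags[which.max(c(r2_t1, r2_t2))])
  expect_equal(row$r2, max(r2_t1, r2_t2))
})

test_that("planted LD partners are recovered across seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (seed in seq_len(n_seeds)) {
    cfg <- sim_config(n_per_population = c(A = 400L), fst = 0,
                      n_chromosomes = 1L, loci_per_chromosome = 120L,
                      ld_rho = 0.894, missing_rate = 0.02,
                      population_means = 100, seed = 600L + seed)
    g <- simulate_genotypes(cfg)
    genes <- synthetic_gene_models(cfg)
    tag <- g$loci$id[50]   # pos 50000, inside gene 40001..70000
    partner <- g$loci$id[51]
    res <- expand_tags(tag, g, genes, r2_min = 0.5)
    if (partner %in% res$combined$snp[res$combined$source == "linked"]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 0.9 * n_seeds)
})
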