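test_that("two-class ANOVA reduces to the pooled-variance t test (F = t^2)", {
  set.seed(71)
  w <- c(rnorm(8, 10), rnorm(6, 12))
  cls <- rep(c("AA", "AG"), c(8, 6))
  res <- anova_lsd(w, cls)
  tt <- t.test(w ~ cls, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$lsd["AA", "AG"], tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA and LSD match a from-scratch sums-of-squares oracle", {
  set.seed(72)
  n <- c(5L, 8L, 6L)
  mu <- c(10, 12, 11)
  w <- unlist(mapply(function(nn, m) rnorm(nn, m), n, mu))
  cls <- rep(c("AA", "AG", "GG"), n)
  res <- anova_lsd(w, cls)

  means <- tapply(w, cls, mean)
  grand <- mean(w)
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((w - means[cls])^2)
  df1 <- 2L; df2 <- length(w) - 3L
  f_oracle <- (ssb / df1) / (ssw / df2)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$p, pf(f_oracle, df1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  mse <- ssw / df2
  for (pair in list(c("AA", "AG"), c("AA", "GG"), c("AG", "GG"))) {
    ni <- n[match(pair, c("AA", "AG", "GG"))]
    tij <- (means[pair[1]] - means[pair[2]]) / sqrt(mse * sum(1 / ni))
    expect_equal(res$lsd[pair[1], pair[2]], unname(2 * pt(-abs(tij), df2)),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA respects class-size gating and degenerate inputs", {
  w <- rnorm(10)
  cls <- c(rep("AA", 7), rep("AG", 2), "GG")
  res <- anova_lsd(w, cls, min_class_n = 3L)
  expect_equal(res$status, "not_testable")
  expect_setequal(res$dropped_classes, c("AG", "GG"))
  expect_true(is.na(res$p))

  # identical class means: F ~ 0, p ~ 1
  w2 <- rep(c(1, 2, 3), 4)
  cls2 <- rep(c("AA", "GG"), each = 6)
  res2 <- anova_lsd(w2, cls2)
  expect_lt(res2$F, 1e-20)
  expect_gt(res2$p, 0.999)

  # p is invariant under adding a constant
  set.seed(73)
  w3 <- rnorm(20)
  cls3 <- rep(c("AA", "AG"), 10)
  expect_equal(anova_lsd(w3 + 100, cls3)$p, anova_lsd(w3, cls3)$p,
               tolerance = 1e-12)
})

test_that("superior genotypes are the significant argmax with documented ties", {
  test_ok <- list(status = "ok", p = 0.01,
                  class_stats = data.frame(class = c("AA", "AG", "GG"),
                                           n = c(10L, 12L, 8L),
                                           mean = c(5, 7, 6)))
  expect_equal(as.character(call_superior_genotype(test_ok)), "AG")
  test_ns <- test_ok; test_ns$p <- 0.20
  expect_true(is.na(call_superior_genotype(test_ns)))

  test_tie <- test_ok
  test_tie$class_stats$mean <- c(7, 7, 6)
  sup <- call_superior_genotype(test_tie)
  expect_equal(as.character(sup), "AG")  # larger n wins the tie
  expect_true(attr(sup, "tie"))
})

test_that("per-population genotype frequencies tally correctly", {
  freqs <- genotype_freqs_by_population(c(0, 0, 1, 2), rep("P1", 4), "G", "C")
  expect_equal(unname(freqs$freqs["P1", ]), c(0.5, 0.25, 0.25))
  expect_equal(colnames(freqs$freqs), c("GG", "GC", "CC"))
  expect_equal(sum(freqs$counts), 4L)

  expect_message(
    f2 <- genotype_freqs_by_population(c(0, 1, NA, NA), c("A", "A", "B", "B"),
                                       "A", "T"),
    "no called"
  )
  expect_true(all(is.na(f2$freqs["B", ])))
  expect_equal(unname(f2$freqs["A", ]), c(0.5, 0.5, 0))
})

test_that("population uniqueness requires presence in exactly one population", {
  counts <- rbind(HLJ = c(5L, 3L, 2L), AH = c(8L, 2L, 0L), HN = c(10L, 0L, 0L))
  colnames(counts) <- c("CC", "CT", "TT")
  expect_true(classify_population_unique(counts, "TT")$unique)
  expect_equal(classify_population_unique(counts, "TT")$population, "HLJ")
  expect_false(classify_population_unique(counts, "CT")$unique)
  expect_error(classify_population_unique(counts, "GG"), "absent")
  zero <- counts; zero[, "TT"] <- 0L
  expect_error(classify_population_unique(zero, "TT"), "not observed")
})

test_that("marker calls maintain the containment hierarchy and determinism", {
  cfg <- quick_config(
    seed = 74, heritability = 0.4, ld_rho = 0.8,
    causal_spec = data.frame(locus = c(30L, 120L), effect = c(0.9, 0.7))
  )
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  f <- apply_filters(g)$table
  G <- compute_grm(f)
  X <- suppressMessages(build_design(ph))
  fit <- fit_lmm_reml(ph$weight_g, X, G)
  adj <- adjust_phenotypes(fit)
  candidates <- f$loci$id[seq(1, n_loci(f), by = 4)]
  calls <- call_markers(f, candidates, adj)

  expect_true(all(calls$snp[calls$population_unique] %in%
                    calls$snp[calls$growth_related]))
  expect_true(all(calls$snp[calls$growth_related] %in% calls$snp))
  expect_true(all(!is.na(calls$superior_genotype[calls$growth_related])))
  expect_true(all(is.na(calls$superior_genotype[!calls$growth_related])))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  report_markers(calls, dir1)
  report_markers(calls, dir2)
  for (fn in c("candidate_markers.tsv", "growth_related_markers.tsv",
               "population_unique_markers.tsv")) {
    expect_identical(readLines(file.path(dir1, fn)),
                     readLines(file.path(dir2, fn)))
  }
  gr <- read.delim(file.path(dir1, "growth_related_markers.tsv"))
  expect_equal(nrow(gr), sum(calls$growth_related))
})

test_that("empty candidate sets produce valid empty reports", {
  cfg <- quick_config(seed = 75)
  g <- simulate_genotypes(cfg)
  calls <- call_markers(g, character(0), rnorm(nrow(g$dosage)))
  expect_equal(nrow(calls), 0L)
  dir <- withr::local_tempdir()
  paths <- report_markers(calls, dir)
  for (p in paths) {
    lines <- readLines(p)
    expect_equal(length(lines), 1L)  # header only
    expect_match(lines[1], "snp\t")
  }
})

test_that("under a global null the growth-related rate is near alpha", {
  set.seed(76)
  n_seeds <- 50L
  m <- 40L
  n <- 90L
  total <- 0L; called <- 0L
  for (s in seq_len(n_seeds)) {
    dos <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n)]),
                  nrow = n)
    tab <- make_table(dos, populations = rep(c("A", "B", "C"), each = 30))
    w <- rnorm(n)
    calls <- call_markers(tab, tab$loci$id, w)
    testable <- calls$status == "ok"
    total <- total + sum(testable)
    called <- called + sum(calls$growth_related[testable])
  }
  expect_lt(abs(called / total - 0.05), 0.02)
})
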