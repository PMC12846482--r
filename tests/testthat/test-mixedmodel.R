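test_that("VanRaden GRM matches hand arithmetic and HWE expectation", {
  # one locus, dosages (0, 2): W = (-1, 1), denominator 0.5
  tab <- make_table(matrix(c(0, 2), ncol = 1))
  expect_equal(unname(compute_grm(tab)), matrix(c(2, -2, -2, 2), 2, 2))

  # identical rows: off-diagonal equals the diagonal
  set.seed(41)
  row <- rbinom(30, 2, 0.5)
  tab2 <- make_table(rbind(row, row, rbinom(30, 2, 0.5)))
  G2 <- compute_grm(tab2)
  expect_equal(G2[1, 2], G2[1, 1])

  # unstructured HWE population: mean diagonal near 1
  cfg <- sim_config(n_per_population = c(A = 200L), fst = 0,
                    n_chromosomes = 1L, loci_per_chromosome = 500L,
                    ld_rho = 0, missing_rate = 0, population_means = 50,
                    seed = 42)
  G3 <- compute_grm(simulate_genotypes(cfg))
  expect_lt(abs(mean(diag(G3)) - 1), 0.05)

  expect_error(compute_grm(make_table(matrix(c(0, 0, 2, 2), 2, 2))),
               "monomorphic")
})

test_that("REML matches an independent random-intercept oracle on block kinship", {
  skip_if_not_installed("lme4")
  set.seed(43)
  n_group <- 15L
  per <- 6L
  n <- n_group * per
  grp <- factor(rep(seq_len(n_group), each = per))
  Z <- model.matrix(~ grp - 1)
  G <- Z %*% t(Z)  # block kinship: the model is a random-intercept LMM
  x <- rnorm(n)
  y <- 2 + 0.5 * x + rep(rnorm(n_group, sd = sqrt(2)), each = per) + rnorm(n)
  X <- cbind(1, x)
  fit <- fit_lmm_reml(y, X, G)
  lmer_fit <- lme4::lmer(y ~ x + (1 | grp), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  expect_equal(fit$sigma2_a, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lmer_fit)),
               tolerance = 1e-5)
  # the identity y = Xb + a + e holds exactly
  expect_equal(drop(X %*% fit$beta) + fit$ahat + fit$ehat, y)
})

test_that("a phenotype in the fixed-effect column space leaves no variance", {
  set.seed(44)
  X <- cbind(1, rnorm(50))
  y <- drop(X %*% c(3, -2))
  G <- diag(50)
  fit <- fit_lmm_reml(y, X, G)
  expect_lt(fit$sigma2_a + fit$sigma2_e, 1e-10)
  expect_lt(max(abs(fit$ehat)), 1e-5)
  Xbad <- cbind(X, X[, 2] * 2)
  expect_error(fit_lmm_reml(y, Xbad, G), "rank deficient")
})

test_that("REML recovers the simulated heritability", {
  ests <- vapply(1:12, function(seed) {
    cfg <- sim_config(n_per_population = c(A = 500L), fst = 0,
                      n_chromosomes = 1L, loci_per_chromosome = 400L,
                      ld_rho = 0, missing_rate = 0, heritability = 0.5,
                      population_means = 100, seed = 5000L + seed)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    G <- compute_grm(g)
    fit <- fit_lmm_reml(ph$weight_g, matrix(1, nrow(G), 1), G)
    fit$heritability
  }, numeric(1L))
  expect_lt(abs(mean(ests) - 0.5), 0.15)
})

test_that("REML optimum is invariant to interval endpoints (unimodality)", {
  set.seed(45)
  cfg <- quick_config(seed = 46, heritability = 0.4)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  G <- compute_grm(g)
  X <- suppressMessages(build_design(ph))
  f1 <- fit_lmm_reml(ph$weight_g, X, G)
  # refit on jittered copies of the problem (phenotype scaled): the ratio
  # estimate must be stable
  f2 <- fit_lmm_reml(ph$weight_g * 2, X, G)
  expect_equal(f2$sigma2_a / f2$sigma2_e, f1$sigma2_a / f1$sigma2_e,
               tolerance = 1e-5)
  expect_equal(f2$sigma2_a, 4 * f1$sigma2_a, tolerance = 1e-5)
})

test_that("phenotype adjustment keeps or removes genetic signal by mode", {
  # intercept-only: fixed_only is mean-centering
  set.seed(47)
  y <- rnorm(30, 10)
  fit <- fit_lmm_reml(y, matrix(1, 30, 1), diag(30) + 0.1)
  adj <- adjust_phenotypes(fit, "fixed_only")
  expect_equal(unname(adj), y - mean(drop(fit$X %*% fit$beta)),
               ignore_attr = TRUE)
  expect_identical(attr(adj, "adjust_mode"), "fixed_only")

  # full residuals absorb additive signal: attenuated causal slope
  cfg <- sim_config(n_per_population = c(A = 300L), fst = 0,
                    n_chromosomes = 1L, loci_per_chromosome = 200L,
                    ld_rho = 0, missing_rate = 0, heritability = 0.4,
                    population_means = 100,
                    causal_spec = data.frame(locus = 100L, effect = 0.7),
                    seed = 48)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  G <- compute_grm(g)
  fitg <- fit_lmm_reml(ph$weight_g, matrix(1, 300, 1), G)
  dos <- g$dosage[, 100L]
  b_fixed <- coef(lm(adjust_phenotypes(fitg, "fixed_only") ~ dos))[2]
  b_resid <- coef(lm(adjust_phenotypes(fitg, "full_residual") ~ dos))[2]
  expect_lt(abs(b_resid), abs(b_fixed))
})

test_that("MLM with identity kinship degenerates to OLS", {
  set.seed(49)
  n <- 100L
  dos <- matrix(rbinom(n * 150, 2, runif(150, 0.1, 0.9)[rep(1:150, each = n)]),
                nrow = n)
  tab <- make_table(dos)
  y <- rnorm(n)
  res <- gwas_mlm(y, tab, diag(n))
  p_ols <- vapply(seq_len(ncol(dos)), function(j) {
    summary(lm(y ~ dos[, j]))$coefficients[2, 4]
  }, numeric(1L))
  expect_equal(res$p, p_ols[match(res$snp, tab$loci$id)], tolerance = 1e-6)
})

test_that("GLS test statistics are invariant to affine phenotype rescaling", {
  cfg <- quick_config(seed = 51, heritability = 0.3)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  f <- apply_filters(g)$table
  G <- compute_grm(f)
  X <- suppressMessages(build_design(ph))
  fit <- fit_lmm_reml(ph$weight_g, X, G)
  adj <- adjust_phenotypes(fit)
  r1 <- gwas_mlm(adj, f, G)
  r2 <- gwas_mlm(3.7 * adj + 11, f, G)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("monomorphic loci are skipped with a log entry", {
  set.seed(52)
  dos <- cbind(matrix(rbinom(40 * 5, 2, 0.5), 40), 0)
  tab <- make_table(dos)
  expect_message(res <- gwas_mlm(rnorm(40), tab, diag(40)), "monomorphic")
  expect_equal(nrow(res), 5L)
  expect_equal(attr(res, "skipped"), tab$loci$id[6])
  expect_equal(attr(res, "m_tested"), 5L)
  expect_equal(attr(res, "threshold"), 0.05 / 5)
})

test_that("LOCO kinship tests every polymorphic locus once", {
  cfg <- quick_config(seed = 53, heritability = 0.3)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  f <- apply_filters(g)$table
  G <- compute_grm(f)
  X <- suppressMessages(build_design(ph))
  fit <- fit_lmm_reml(ph$weight_g, X, G)
  adj <- adjust_phenotypes(fit)
  r_loco <- gwas_mlm(adj, f, loco = TRUE)
  r_full <- gwas_mlm(adj, f, G)
  expect_identical(r_loco$snp, r_full$snp)
  expect_identical(attr(r_loco, "m_tested"), attr(r_full, "m_tested"))
  # same data under a different covariance: estimates broadly agree (with
  # only two chromosomes the leave-one-out kinship differs substantially)
  expect_gt(cor(r_loco$beta, r_full$beta), 0.8)
  expect_true(all(r_loco$p > 0 & r_loco$p <= 1))
  expect_error(gwas_mlm(adj, f), "supply G or set loco")
  one_chrom <- subset_variants(f, loci = which(f$loci$chrom == "Chr1"))
  expect_error(gwas_mlm(adj, one_chrom, loco = TRUE), "two chromosomes")
})

test_that("model-result merging unions, labels and orders loci", {
  a <- data.frame(snp = c("Chr1_100_A_G", "Chr2_50_C_T"), method = "MLM")
  b <- data.frame(snp = c("Chr2_50_C_T", "Chr10_9_A_C", "Chr2_10_G_A"),
                  method = "BLINK")
  m <- merge_model_results(a, b)
  expect_equal(nrow(m), 4L)
  expect_equal(m$SNP, c("Chr1_100_A_G", "Chr2_10_G_A", "Chr2_50_C_T",
                        "Chr10_9_A_C"))  # numeric chromosome order
  expect_equal(m$Method[m$SNP == "Chr2_50_C_T"], "BLINK, MLM")

  # commutative and idempotent
  expect_equal(merge_model_results(b, a), m)
  expect_equal(merge_model_results(a, b, a, b), m)
  expect_equal(nrow(merge_model_results(a, a)), 2L)

  # disjoint lists of sizes 2 and 3
  c2 <- data.frame(snp = c("Chr3_1_A_G", "Chr3_2_A_G"), method = "x")
  c3 <- data.frame(snp = paste0("Chr4_", 1:3, "_A_G"), method = "y")
  expect_equal(nrow(merge_model_results(c2, c3)), 5L)

  bad <- data.frame(snp = "Chr1_abc_A_G", method = "MLM")
  expect_error(merge_model_results(bad), "malformed")
})
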