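# shared fixtures and independent oracles for the test suite

# build a variant_table from a dosage matrix with evenly spaced loci
make_table <- function(dosage, chrom = "Chr1", ref = "A", alt = "G",
                       populations = NULL, spacing = 1000L) {
  m <- ncol(dosage)
  loci <- data.frame(
    chrom = rep_len(chrom, m),
    pos = seq_len(m) * spacing,
    ref = rep_len(ref, m),
    alt = rep_len(alt, m),
    stringsAsFactors = FALSE
  )
  variant_table(loci, dosage, populations = populations)
}

# independent HWE oracle: exhaustive enumeration of the conditional
# distribution of the heterozygote count via the closed-form log
# multinomial/hypergeometric expression (lchoose/lgamma), not the recurrence
hwe_enum_oracle <- function(a, b, c) {
  n <- a + b + c
  nA <- 2 * a + b
  na_ <- 2 * c + b
  rare <- min(nA, na_)
  if (rare == 0) return(1)
  hets <- seq.int(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- (2 * n - rare - h) / 2
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1) +
      h * log(2) +
      lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(b, hets)]
  min(sum(p[p <= obs * (1 + 1e-9)]), 1)
}

# Hudson-style FST estimator for two populations (ratio of averages)
hudson_fst <- function(dosage, populations) {
  pops <- unique(populations)
  stopifnot(length(pops) == 2)
  d1 <- dosage[populations == pops[1], , drop = FALSE]
  d2 <- dosage[populations == pops[2], , drop = FALSE]
  p1 <- colMeans(d1, na.rm = TRUE) / 2
  p2 <- colMeans(d2, na.rm = TRUE) / 2
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}

# default small study-shaped configuration for quick tests
quick_config <- function(seed = 1L, ...) {
  sim_config(n_chromosomes = 2L, loci_per_chromosome = 100L, seed = seed, ...)
}
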