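test_that("internal relatedness matches hand-derived values", {
  # one heterozygous locus with alleles at f = 0.5 each -> IR = -1
  gt1 <- make_gt(list(L = list(c("a", "b"), c("a", "a"), c("b", "b"))))
  expect_equal(internal_relatedness(gt1)[1], -1)
  # fully homozygous at polymorphic loci -> IR = 1
  expect_equal(internal_relatedness(gt1)[2], 1)
  # two loci: hom a (f = 0.25), het c/d (f = 0.5, 0.25) -> 0.75/2.75
  freqs <- list(L1 = c(a = 0.25, b = 0.75), L2 = c(c = 0.5, d = 0.25, e = 0.25))
  gt2 <- make_gt(list(L1 = list(c("a", "a")), L2 = list(c("c", "d"))))
  expect_equal(internal_relatedness(gt2, freqs), (2 - 1.25) / (4 - 1.25))
})

test_that("IR is invariant to locus order, allele relabeling, and monomorphic loci", {
  ds <- simulate_dataset(sim_config(n_individuals = 30, n_loci = 8, seed = 13))
  gt <- ds$table
  ir <- internal_relatedness(gt)
  # locus order
  ord <- c(5, 2, 8, 1, 7, 3, 6, 4)
  gt_o <- genotype_table(gt$meta, gt$a1[, ord], gt$a2[, ord])
  expect_equal(internal_relatedness(gt_o), ir)
  # relabeling alleles at locus 1
  relab <- function(m) {
    ok <- !is.na(m[, 1])
    m[ok, 1] <- paste0("z", m[ok, 1])
    m
  }
  gt_r <- genotype_table(gt$meta, relab(gt$a1), relab(gt$a2))
  expect_equal(internal_relatedness(gt_r), ir)
  # appending a monomorphic locus changes nothing
  mono1 <- cbind(gt$a1, MONO = "9"); mono2 <- cbind(gt$a2, MONO = "9")
  gt_m <- genotype_table(gt$meta, mono1, mono2)
  expect_equal(internal_relatedness(gt_m), ir)
})

test_that("mean IR on outbred data matches an enumeration oracle", {
  # 4 biallelic loci: enumerate all 3^4 genotype combinations under HWE,
  # compute exact E[IR], and compare the simulated mean
  p1 <- c(0.7, 0.8, 0.55, 0.3)  # frequency of allele "1" per locus
  n <- 4000
  set.seed(17)
  a1 <- a2 <- matrix(NA_character_, n, 4,
                     dimnames = list(NULL, paste0("L", 1:4)))
  for (j in 1:4) {
    a1[, j] <- sample(c("1", "2"), n, TRUE, c(p1[j], 1 - p1[j]))
    a2[, j] <- sample(c("1", "2"), n, TRUE, c(p1[j], 1 - p1[j]))
  }
  meta <- data.frame(id = as.character(seq_len(n)), sex = "female",
                     year = 2006L, age = 2, litter_size = NA_integer_)
  gt <- genotype_table(meta, a1, a2)
  freqs <- lapply(p1, function(p) c(`1` = p, `2` = 1 - p))
  names(freqs) <- paste0("L", 1:4)
  # oracle: exact expectation over all genotype combinations
  combos <- expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2, g4 = 0:2) # copies of allele "1"
  e_ir <- 0
  for (r in seq_len(nrow(combos))) {
    prob <- 1; H <- 0; sumf <- 0
    for (j in 1:4) {
      g <- combos[r, j]
      prob <- prob * stats::dbinom(g, 2, p1[j])
      if (g != 1) H <- H + 1
      sumf <- sumf + g * p1[j] + (2 - g) * (1 - p1[j])
    }
    e_ir <- e_ir + prob * (2 * H - sumf) / (8 - sumf)
  }
  ir <- internal_relatedness(gt, freqs)
  expect_lt(abs(mean(ir) - e_ir), 3 * stats::sd(ir) / sqrt(n))
})

test_that("sMLH definition, normalization and HL weighting behave as defined", {
  gt <- make_gt(list(L1 = list(c("a", "b"), c("a", "a")),
                     L2 = list(c("c", "d"), c("c", "c"))))
  # all loci mean het 0.5: fully heterozygous individual scores 2
  expect_equal(smlh(gt, locus_ho = c(0.5, 0.5))[1], 2)
  # an individual whose het pattern equals the locus means scores 1
  gt_eq <- make_gt(list(L1 = list(c("a", "b")), L2 = list(c("c", "c"))))
  expect_equal(smlh(gt_eq, locus_ho = c(1, 0))[1], 1)
  # population mean sMLH over complete data is 1
  ds <- simulate_dataset(sim_config(n_individuals = 50, n_loci = 6,
                                    missing_rate = 0, seed = 19))
  expect_equal(mean(smlh(ds$table)), 1)
  # HL: fully het -> 0; fully hom -> 1; weighted example 0.6/0.8
  expect_equal(hl(gt)[1], 0)
  expect_equal(hl(gt)[2], 1)
  gt3 <- make_gt(list(L1 = list(c("a", "a")), L2 = list(c("c", "d"))))
  expect_equal(hl(gt3, locus_uhe = c(0.6, 0.2)), 0.6 / 0.8)
})

test_that("heterozygosity indices are near-collinear and IR runs against sMLH", {
  ds <- simulate_dataset(sim_config(seed = 23))
  m <- mlh(ds$table)
  cc <- mlh_correlations(m)
  expect_equal(diag(cc), c(ir = 1, smlh = 1, hl = 1))
  expect_equal(cc, t(cc))
  expect_lt(cc["ir", "smlh"], 0)           # IR is homozygosity-directed
  expect_true(all(abs(cc) >= 0.9))         # strongly collinear indices
})

test_that("year trend regression handles perfect, null and degenerate cases", {
  years <- rep(2006:2010, each = 4)
  fit <- suppressWarnings(index_year_trend(as.numeric(years), years))
  expect_equal(fit$slope, 1)
  expect_lt(fit$p_slope, 1e-10)
  # constant response: no trend, reported as slope 0 with p = 1
  fit0 <- index_year_trend(rep(0.3, 20), years)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$p_slope, 1)
  # single sampling year: undefined slope
  expect_warning(fit1 <- index_year_trend(rnorm(5), rep(2006, 5)), "single")
  expect_true(is.na(fit1$slope))
  # OLS agreement with lm on noisy data
  set.seed(29)
  y <- 0.01 * years + rnorm(20, sd = 0.1)
  fit2 <- index_year_trend(y, years)
  ref <- summary(stats::lm(y ~ years))$coefficients
  expect_equal(fit2$slope, ref["years", 1])
  expect_equal(fit2$slope_se, ref["years", 2])
})
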