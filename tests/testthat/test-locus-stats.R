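test_that("per-locus summary matches hand-computed Ho and unbiased He", {
  gt <- make_gt(list(L1 = list(c("a", "a"), c("a", "b"), c("b", "b"), c("a", "b")),
                     M1 = list(c("x", "x"), c("x", "x"), c("x", "x"), c("x", "x"))))
  ls <- locus_summary(gt)
  expect_equal(ls$ho[1], 0.5)
  expect_equal(ls$uhe[1], (8 / 7) * 0.5)
  expect_equal(ls$na[1], 2L)
  # monomorphic locus
  expect_equal(ls$ho[2], 0)
  expect_equal(ls$uhe[2], 0)
  expect_equal(ls$na[2], 1L)
  expect_true(is.na(ls$hwe_p[2]))
  expect_true(ls$monomorphic[2])
})

test_that("unbiased He equals the loop-based definition on random tables", {
  ds <- simulate_dataset(sim_config(n_individuals = 60, n_loci = 10, seed = 9))
  ls <- locus_summary(ds$table, n_mc = 200)
  for (j in seq_len(10)) {
    a1 <- ds$table$a1[, j]; a2 <- ds$table$a2[, j]
    typed <- !is.na(a1)
    n <- sum(typed)
    alle <- c(a1[typed], a2[typed])
    sum_p2 <- 0
    for (a in unique(alle)) sum_p2 <- sum_p2 + (sum(alle == a) / (2 * n))^2
    expect_equal(ls$uhe[j], (2 * n / (2 * n - 1)) * (1 - sum_p2))
  }
})

test_that("HWE exact test: enumeration matches hand-derived probabilities", {
  # AA=2, aa=2: weights over het counts {0,2,4} are {6,48,16}/70; obs is least likely
  p <- hwe_exact_test(rep(c("A", "a"), each = 2), rep(c("A", "a"), each = 2))
  expect_equal(p$p.value, 6 / 70)
  expect_identical(p$method, "enumeration")
  # observed configuration at HWE proportions is modal -> p near 1
  a1 <- c(rep("A", 25), rep("A", 50), rep("a", 25))
  a2 <- c(rep("A", 25), rep("a", 50), rep("a", 25))
  expect_gt(hwe_exact_test(a1, a2)$p.value, 0.9)
})

test_that("Monte-Carlo HWE p agrees with enumeration on a 3-allele locus", {
  set.seed(4)
  pool <- sample(rep(c("a", "b", "c"), times = c(30, 20, 10)))
  a1 <- pool[1:30]; a2 <- pool[31:60]
  enum <- hwe_exact_test(a1, a2, method = "enum")$p.value
  mc <- hwe_exact_test(a1, a2, method = "mc", n_mc = 4000, seed = 8)$p.value
  se <- sqrt(enum * (1 - enum) / 4000)
  expect_lt(abs(mc - enum), 3 * se + 1 / 4001)
})

test_that("HWE exact p is uniform or super-uniform under the null", {
  set.seed(11)
  rej <- 0
  for (r in 1:1000) {
    g1 <- sample(c("A", "a"), 50, replace = TRUE, prob = c(0.6, 0.4))
    g2 <- sample(c("A", "a"), 50, replace = TRUE, prob = c(0.6, 0.4))
    p <- hwe_exact_test(g1, g2)$p.value
    if (!is.na(p) && p <= 0.05) rej <- rej + 1
  }
  expect_lte(rej / 1000, 0.07)
})

test_that("Nei F_IS: hand example, HWE cohort near zero, and upper bound", {
  # two individuals AA and aa: Ho = 0, Hs = 1 -> F_IS = 1
  gt <- make_gt(list(L = list(c("A", "A"), c("a", "a"))), year = c(2006L, 2006L))
  fis <- nei_fis(gt)
  expect_equal(unname(fis$fis["L", "2006"]), 1)
  # outbred simulated cohorts: mean F_IS across loci close to 0, never > 1
  cfg <- sim_config(n_individuals = 400, n_loci = 32, missing_rate = 0,
                    f_dist = list(type = "discrete", values = 0, probs = 1),
                    years = 2006L, year_weights = 1, seed = 21)
  f2 <- nei_fis(simulate_dataset(cfg)$table)
  expect_true(all(f2$fis <= 1, na.rm = TRUE))
  expect_lt(abs(f2$cohort_mean), 3 * stats::sd(f2$fis[, 1], na.rm = TRUE) /
              sqrt(sum(!is.na(f2$fis))))
})

test_that("Brookfield null-allele estimator: arithmetic and clamping", {
  expect_equal(brookfield_null(0.5, 0.5), 0)          # no deficit
  expect_equal(brookfield_null(0.340, 0.378), 0.038 / 1.378)
  expect_equal(brookfield_null(0, 0.5), 1 / 3)
  expect_equal(brookfield_null(0.6, 0.4), 0)          # negative clamped
})

test_that("per-cohort null table recovers a simulated null-allele frequency", {
  cfg <- sim_config(n_individuals = 1000, n_loci = 16, missing_rate = 0,
                    na_values = 4:6, na_weights = c(1, 1, 1),
                    freq_concentration = 5,
                    f_dist = list(type = "discrete", values = 0, probs = 1),
                    years = 2006L, year_weights = 1,
                    null_allele_rate = 0.2, seed = 31)
  nt <- null_allele_table(simulate_dataset(cfg)$table)
  # Brookfield 1 targets r/(1+He)-scale deficits; recovery is approximate
  expect_gt(mean(nt$`2006`, na.rm = TRUE), 0.10)
  expect_lt(mean(nt$`2006`, na.rm = TRUE), 0.30)
})
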