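test_that("Gelman standardization: example values, SD 0.5, slope rescaling", {
  expect_equal(gelman_standardize(c(0, 10)),
               c(-5, 5) / (2 * stats::sd(c(0, 10))))
  set.seed(3)
  x <- rnorm(50, 10, 4)
  z <- gelman_standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(stats::sd(z), 0.5)
  expect_error(gelman_standardize(rep(2, 5)), "variance")
  # slope on the standardized scale = raw slope * 2 SD(x)
  d <- data.frame(litter_size = rbinom(50, 4, stats::plogis(1 - 0.2 * x)),
                  x = x)
  dz <- transform(d, x = gelman_standardize(x))
  b_raw <- fit_binomial_glm(d, "x", "litter")$coefficients[["x"]]
  b_std <- fit_binomial_glm(dz, "x", "litter")$coefficients[["x"]]
  expect_equal(b_std, b_raw * 2 * stats::sd(x), tolerance = 1e-8)
})

test_that("intercept-only binomial fits equal pooled-proportion logits", {
  d <- data.frame(litter_size = rep(1L, 12))
  expect_equal(fit_binomial_glm(d, response = "litter")$coefficients[["(Intercept)"]],
               stats::qlogis(0.25), tolerance = 1e-10)
  d2 <- data.frame(litter_size = rep(c(0L, 2L), 10))  # half bred
  expect_equal(fit_binomial_glm(d2, response = "bred")$coefficients[["(Intercept)"]],
               0, tolerance = 1e-10)
})

test_that("binomial GLM matches an independent IRLS oracle", {
  set.seed(67)
  for (r in 1:5) {
    n <- 30
    d <- data.frame(age = rnorm(n), ir = rnorm(n), year = rnorm(n))
    eta <- 0.5 - 0.8 * d$ir + 0.3 * d$age - 0.5 * d$year
    d$litter_size <- rbinom(n, 4, stats::plogis(eta))
    fit <- fit_binomial_glm(d, c("age", "ir", "year"), "litter")
    orac <- irls_fit(cbind(1, as.matrix(d[c("age", "ir", "year")])),
                     d$litter_size, 4)
    expect_equal(unname(fit$coefficients), unname(orac$coefficients),
                 tolerance = 1e-8)
    expect_equal(unname(fit$se), unname(orac$se), tolerance = 1e-4)
  }
})

test_that("events/trials and four-Bernoulli-rows encodings give identical slopes", {
  set.seed(71)
  n <- 40
  d <- data.frame(x = rnorm(n))
  d$litter_size <- rbinom(n, 4, stats::plogis(0.4 + 0.9 * d$x))
  fit <- fit_binomial_glm(d, "x", "litter")
  long <- data.frame(x = rep(d$x, each = 4),
                     y = unlist(lapply(d$litter_size, function(k)
                       rep(c(1, 0), c(k, 4 - k)))))
  ref <- stats::glm(y ~ x, binomial(), long)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # the binomial constant enters the likelihood: AIC differs from the
  # Bernoulli encoding only through that constant
  expect_equal(fit$aic,
               stats::AIC(ref) - 2 * sum(lchoose(4, d$litter_size)),
               tolerance = 1e-6)
})

test_that("model averaging: weights, RI arithmetic and conditional averages", {
  set.seed(73)
  n <- 80
  d <- data.frame(age = rnorm(n), ir = rnorm(n), year = rnorm(n))
  d$litter_size <- rbinom(n, 4, stats::plogis(0.5 - 1.5 * d$ir - 0.8 * d$year))
  av <- all_subsets_average(d, "litter", c("age", "ir", "year"))
  expect_equal(sum(av$candidates$weight), 1)
  expect_equal(nrow(av$candidates), 8L)
  expect_true(all(av$terms$ri[-1] >= 0 & av$terms$ri[-1] <= 1))
  # RI of a term = sum of weights of the models containing it
  w_ir <- sum(av$candidates$weight[grepl("ir", av$candidates$model)])
  expect_equal(av$terms$ri[av$terms$term == "ir"], w_ir)
  # intercept appears in every model: its conditional average is the
  # full-set weighted mean of per-model estimates
  ests <- vapply(seq_len(8), function(m) {
    preds <- strsplit(av$candidates$model[m], "+", fixed = TRUE)[[1]]
    preds <- setdiff(preds, "(intercept)")
    fit_binomial_glm(d, preds, "litter")$coefficients[["(Intercept)"]]
  }, numeric(1))
  expect_equal(av$terms$estimate[av$terms$term == "(Intercept)"],
               sum(av$candidates$weight * ests))
  # adjusted-SE CI bounds are estimate +/- 1.96 adjSE
  expect_equal(av$terms$ci_hi - av$terms$estimate, 1.96 * av$terms$adj_se)
})

test_that("GLM R2 is near 0 without signal and near 1 near saturation", {
  set.seed(79)
  d0 <- data.frame(x = rnorm(200))
  d0$litter_size <- rbinom(200, 4, 0.5)
  f0 <- fit_binomial_glm(d0, "x", "litter")
  expect_lt(abs(glm_r2(f0)), 0.05)
  expect_lt(abs(glm_r2(f0, "kl")), 0.05)
  # strong signal: both flavours report most of the variation explained,
  # approaching 1 as the fit saturates (deviance-based form is the stable
  # one near saturation, where fitted probabilities touch 0/1)
  d1 <- data.frame(x = rnorm(200))
  d1$litter_size <- rbinom(200, 4, stats::plogis(4 * d1$x))
  f1 <- fit_binomial_glm(d1, "x", "litter")
  expect_gt(glm_r2(f1, "kl"), 0.5)
  expect_gt(glm_r2(f1, "v"), 0.5)
  d2 <- data.frame(x = rnorm(200))
  d2$litter_size <- ifelse(d2$x > 0, 4L, 0L)
  d2$litter_size[1:2] <- c(3L, 1L)  # avoid complete separation
  f2 <- suppressWarnings(fit_binomial_glm(d2, "x", "litter"))
  expect_gt(glm_r2(f2, "kl"), 0.8)
})

test_that("CI-exclusion power under a strong load matches a Wald power oracle", {
  ## oracle: estimate the attenuated standardized IR effect and per-study SE
  ## from one very large cohort, then predict Wald power at n = 90
  b_f <- -6
  big <- simulate_dataset(sim_config(n_individuals = 20000, prop_female = 1,
                                     b_f = b_f, seed = 311))
  rec <- mlh(big$table)
  m <- big$table$meta
  d <- data.frame(litter_size = m$litter_size, age = m$age, ir = rec$ir,
                  year = m$year - 2006)
  for (v in c("age", "ir", "year")) d[[v]] <- gelman_standardize(d[[v]])
  f_big <- fit_binomial_glm(d, c("age", "ir", "year"), "litter")
  beta <- f_big$coefficients[["ir"]]
  se90 <- f_big$se[["ir"]] * sqrt(20000 / 90)
  power_oracle <- stats::pnorm(abs(beta) / se90 - 1.96)
  ## empirical: rate at which the averaged-coefficient CI excludes zero
  n_rep <- 200L
  excl <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_individuals = 90, prop_female = 1, b_f = b_f,
                      seed = 900000 + r)
    ds <- simulate_dataset(cfg)
    rr <- mlh(ds$table)
    mm <- ds$table$meta
    dd <- data.frame(litter_size = mm$litter_size, age = mm$age, ir = rr$ir,
                     year = mm$year - 2006)
    dd <- dd[stats::complete.cases(dd), ]
    for (v in c("age", "ir", "year")) dd[[v]] <- gelman_standardize(dd[[v]])
    av <- all_subsets_average(dd, "litter", c("age", "ir", "year"))
    est <- av$terms[av$terms$term == "ir", ]
    if (est$estimate < 0 && est$ci_hi < 0) excl <- excl + 1L
  }
  expect_lt(abs(excl / n_rep - power_oracle), 0.10)
})

test_that("reproductive model set runs end to end with sensible shapes", {
  ds <- simulate_dataset(sim_config(seed = 83))
  hfc <- run_reproductive_models(ds$table)
  expect_s3_class(hfc, "hfc_fit")
  expect_equal(hfc$litter_all$n, sum(ds$table$meta$sex == "female" &
                                       !is.na(ds$table$meta$litter_size)))
  expect_equal(hfc$litter_breeders$n, sum(ds$table$meta$litter_size >= 1,
                                          na.rm = TRUE))
  for (nm in c("litter_all", "breeding", "litter_breeders"))
    expect_equal(sum(hfc[[nm]]$candidates$weight), 1)
  # year effect is simulated negative and strong: RI should reflect it
  expect_lt(hfc$litter_all$terms$estimate[hfc$litter_all$terms$term == "year"], 0)
})
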