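#' Gelman standardization
#'
#' Centers and scales by twice the standard deviation, `(x - mean) / (2 SD)`,
#' so a one-unit change in a standardized continuous predictor is comparable
#' to a binary predictor's 0/1 contrast. The result has mean 0 and SD 0.5.
#'
#' @param x numeric vector with at least two distinct values.
#' @return standardized vector.
#' @export
gelman_standardize <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("cannot standardize a vector with zero variance")
  (x - mean(x, na.rm = TRUE)) / (2 * stats::sd(x, na.rm = TRUE))
}

#' Fit one binomial logit model
#'
#' Maximum-likelihood logistic fit. For litter-size responses the count of
#' offspring is the number of binomial events out of 4 trials (the maximum
#' litter size), via `cbind(events, 4 - events)`; the breeding response is
#' Bernoulli (litter size >= 1). The log-likelihood includes the binomial
#' combinatorial constant, so AIC follows mainstream GLM conventions.
#'
#' @param data data.frame containing the response column and predictors.
#' @param predictors character vector of predictor column names (possibly
#'   empty, for an intercept-only model).
#' @param response `"litter"` (events out of 4) or `"bred"` (Bernoulli on
#'   litter_size >= 1). The litter column must be named `litter_size`.
#' @return list of class `binom_fit`: `coefficients`, `se`, `loglik`, `k`,
#'   `aic`, `aicc`, `n`, `converged`, `deviance`, `null_deviance`, `glm`
#'   (the underlying [stats::glm] object).
#' @export
fit_binomial_glm <- function(data, predictors = character(0),
                             response = c("litter", "bred")) {
  response <- match.arg(response)
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  lhs <- if (response == "litter") "cbind(litter_size, 4 - litter_size)"
  else "I(litter_size >= 1)"
  fml <- stats::as.formula(paste(lhs, "~", rhs))
  fit <- stats::glm(fml, family = stats::binomial(), data = data)
  if (!fit$converged) stop("binomial GLM did not converge: ", deparse(fml))
  sm <- summary(fit)
  se <- sm$coefficients[, 2]
  names(se) <- rownames(sm$coefficients)  # 1-row matrices drop names
  k <- length(stats::coef(fit))
  n <- stats::nobs(fit)
  ll <- as.numeric(stats::logLik(fit))
  aic <- -2 * ll + 2 * k
  structure(list(coefficients = stats::coef(fit),
                 se = se,
                 loglik = ll, k = k,
                 aic = aic,
                 aicc = aic + 2 * k * (k + 1) / (n - k - 1),
                 n = n, converged = fit$converged,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 glm = fit),
            class = "binom_fit")
}

#' Variance-function or deviance R-squared for a binomial GLM
#'
#' Default `"v"` is the variance-function-based R-squared: one minus the
#' ratio of Pearson-type discrepancies \eqn{\sum w (y - \mu)^2 / V(\mu)}
#' between the fitted and the intercept-only model (w = prior trial
#' weights, V the binomial variance function). `"kl"` is the
#' deviance-based (Kullback-Leibler) form `1 - D / D_0`. The method used is
#' recorded as an attribute.
#'
#' @param fit a `binom_fit` from [fit_binomial_glm()].
#' @param method `"v"` (default) or `"kl"`.
#' @return R-squared (scalar) with attribute `"method"`.
#' @export
glm_r2 <- function(fit, method = c("v", "kl")) {
  method <- match.arg(method)
  g <- fit$glm
  if (method == "kl") {
    r2 <- 1 - g$deviance / g$null.deviance
  } else {
    y <- g$y                              # proportion scale
    w <- stats::weights(g)                # prior trial counts
    mu <- stats::fitted(g)
    mu0 <- sum(w * y) / sum(w)            # intercept-only MLE: pooled proportion
    disc <- function(m) sum(w * (y - m)^2 / (m * (1 - m)))
    r2 <- 1 - disc(mu) / disc(mu0)
  }
  structure(r2, method = method)
}

#' All-subsets fitting and conditional model averaging
#'
#' Fits all subsets of the predictor set (intercept always included),
#' ranks them by AICc (or AIC), and produces a conditionally averaged
#' coefficient table. Akaike weights are
#' \eqn{w_m = \exp(-\Delta_m/2) / \sum \exp(-\Delta/2)}. For each term the
#' conditional (natural) average is taken over the models containing it,
#' with weights renormalized; the adjusted SE follows the standard
#' unconditional-variance estimator
#' \eqn{\sum \tilde w_m \sqrt{SE_m^2 + (\beta_m - \bar\beta)^2}}; 95%
#' confidence bounds are the estimate +/- 1.96 adjusted SE; relative
#' importance (RI) is the sum of full-set weights of the models containing
#' the term. The global (all-predictor) model supplies the R-squared.
#'
#' @param data data.frame with the response column and (standardized)
#'   predictors.
#' @param response `"litter"` or `"bred"` (see [fit_binomial_glm()]).
#' @param predictors character vector of predictor column names.
#' @param criterion `"aicc"` (default) or `"aic"`.
#' @param subset_delta optional: restrict averaging to models within this
#'   criterion difference of the best model (default: full candidate set).
#' @param r2_method passed to [glm_r2()].
#' @return object of class `averaged_fit`: `terms` (data.frame with
#'   estimate, adj_se, ci_lo, ci_hi, ri per term), `candidates` (model,
#'   k, criterion value, delta, weight), `r2`, `n`, `criterion`,
#'   `response`.
#' @export
all_subsets_average <- function(data, response, predictors,
                                criterion = c("aicc", "aic"),
                                subset_delta = NULL,
                                r2_method = "v") {
  criterion <- match.arg(criterion)
  stopifnot(length(predictors) >= 1L)
  subsets <- .predictor_subsets(predictors)
  fits <- list(); ok <- logical(length(subsets))
  for (m in seq_along(subsets)) {
    fits[[m]] <- tryCatch(fit_binomial_glm(data, subsets[[m]], response),
                          error = function(e) NULL)
    ok[m] <- !is.null(fits[[m]])
  }
  if (!all(ok)) warning(sum(!ok), " candidate model(s) failed to converge; excluded")
  subsets <- subsets[ok]; fits <- fits[ok]
  crit <- vapply(fits, function(f) if (criterion == "aicc") f$aicc else f$aic,
                 numeric(1))
  delta <- crit - min(crit)
  w <- exp(-delta / 2); w <- w / sum(w)
  keep <- if (is.null(subset_delta)) rep(TRUE, length(w)) else delta <= subset_delta
  terms <- c("(Intercept)", predictors)
  tab <- data.frame(term = terms, estimate = NA_real_, adj_se = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_, ri = NA_real_,
                    stringsAsFactors = FALSE)
  for (t in terms) {
    inm <- vapply(seq_along(subsets), function(m)
      t == "(Intercept)" || t %in% subsets[[m]], logical(1))
    use <- inm & keep
    if (!any(use)) next
    wt <- w[use] / sum(w[use])
    b <- vapply(fits[use], function(f) f$coefficients[[t]], numeric(1))
    s <- vapply(fits[use], function(f) f$se[[t]], numeric(1))
    est <- sum(wt * b)
    adj <- sum(wt * sqrt(s^2 + (b - est)^2))
    i <- which(tab$term == t)
    tab$estimate[i] <- est
    tab$adj_se[i] <- adj
    tab$ci_lo[i] <- est - 1.96 * adj
    tab$ci_hi[i] <- est + 1.96 * adj
    tab$ri[i] <- if (t == "(Intercept)") NA_real_ else sum(w[inm])
  }
  cand <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)", character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    criterion = crit, delta = delta, weight = w,
    stringsAsFactors = FALSE)
  cand <- cand[order(cand$criterion), ]
  global <- fits[[which(vapply(subsets, length, integer(1)) == length(predictors))]]
  structure(list(terms = tab, candidates = cand,
                 r2 = as.numeric(glm_r2(global, r2_method)),
                 r2_method = r2_method,
                 n = global$n, criterion = criterion, response = response,
                 global = global),
            class = "averaged_fit")
}

.predictor_subsets <- function(predictors) {
  p <- length(predictors)
  out <- list(character(0))
  for (k in seq_len(p))
    out <- c(out, utils::combn(predictors, k, simplify = FALSE))
  out
}

#' @export
print.averaged_fit <- function(x, digits = 3, ...) {
  cat(sprintf("conditional model average (%s, %s response, n = %d, global R2 = %.3f [%s])\n",
              toupper(x$criterion), x$response, x$n, x$r2, x$r2_method))
  tab <- x$terms
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Reproductive-success model set
#'
#' Fits the three heterozygosity-fitness model families on female records:
#' (a) litter size (events out of 4) for all females, (b) probability of
#' breeding (litter size >= 1) for all females, and (c) litter size for
#' breeding females only. Predictors are age, internal relatedness (IR) and
#' year (coded 0 at `year_zero` before standardization), all
#' Gelman-standardized; each family is model-averaged over its 8 predictor
#' subsets. Rows with any missing predictor or response are dropped from
#' every candidate model of a family so criterion values are comparable.
#'
#' @param x a [genotype_table()].
#' @param mlh_records optional [mlh()] data.frame (computed when omitted).
#' @param criterion,subset_delta,r2_method see [all_subsets_average()].
#' @param year_zero calendar year coded as 0 (default 2006).
#' @return object of class `hfc_fit`: list with `litter_all`, `breeding`,
#'   `litter_breeders` (each an `averaged_fit`).
#' @export
run_reproductive_models <- function(x, mlh_records = NULL,
                                    criterion = "aicc",
                                    subset_delta = NULL,
                                    r2_method = "v",
                                    year_zero = 2006) {
  if (is.null(mlh_records)) mlh_records <- mlh(x)
  m <- x$meta
  df <- data.frame(litter_size = m$litter_size,
                   age = m$age,
                   ir = mlh_records$ir,
                   year = m$year - year_zero,
                   sex = m$sex, stringsAsFactors = FALSE)
  df <- df[!is.na(df$sex) & df$sex == "female" & !is.na(df$litter_size) &
             !is.na(df$age) & !is.na(df$ir), ]
  if (!nrow(df)) stop("no female records with complete litter size, age and IR")
  std <- df
  for (v in c("age", "ir", "year")) std[[v]] <- gelman_standardize(df[[v]])
  preds <- c("age", "ir", "year")
  breeders <- df$litter_size >= 1
  if (!any(breeders)) stop("no breeding females (litter size >= 1)")
  stdb <- df[breeders, ]
  for (v in preds) stdb[[v]] <- gelman_standardize(stdb[[v]])
  fit <- function(d, response) all_subsets_average(
    d, response, preds, criterion = criterion,
    subset_delta = subset_delta, r2_method = r2_method)
  structure(list(litter_all = fit(std, "litter"),
                 breeding = fit(std, "bred"),
                 litter_breeders = fit(stdb, "litter"),
                 n_all = nrow(std), n_breeders = nrow(stdb),
                 year_zero = year_zero),
            class = "hfc_fit")
}

#' @export
print.hfc_fit <- function(x, ...) {
  cat(sprintf("reproductive-success models: %d females (%d breeders); year 0 = %d\n\n",
              x$n_all, x$n_breeders, x$year_zero))
  for (nm in c("litter_all", "breeding", "litter_breeders")) {
    cat("--", nm, "--\n"); print(x[[nm]]); cat("\n")
  }
  invisible(x)
}

#' Write the averaged model table as TSV
#'
#' Columns: Model, N, Predictor, Estimate, SE, RI, R2 — one block of rows
#' per response family.
#'
#' @param x an `hfc_fit` from [run_reproductive_models()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hfc_table <- function(x, path) {
  blocks <- list("Litter size" = x$litter_all,
                 "Breeding" = x$breeding,
                 "Litter size 1+" = x$litter_breeders)
  rows <- do.call(rbind, lapply(names(blocks), function(nm) {
    av <- blocks[[nm]]
    data.frame(Model = nm, N = av$n,
               Predictor = av$terms$term,
               Estimate = round(av$terms$estimate, 3),
               SE = round(av$terms$adj_se, 3),
               RI = round(av$terms$ri, 2),
               R2 = c(round(av$r2, 3), rep(NA, nrow(av$terms) - 1L)),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
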