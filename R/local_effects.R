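#' Locus-by-locus local-effects model scan
#'
#' Tests whether the heterozygosity-fitness signal is carried by particular
#' loci ("local effects") or by genome-wide inbreeding ("general effects").
#' On the complete-case female subset (no missing genotypes, known litter
#' size), fits with plain AIC:
#' * a "base" binomial model `litter/4 ~ year` (raw year, 0 at `year_zero`),
#' * one single-locus model per polymorphic locus, adding that locus's 0/1
#'   heterozygosity to the base model,
#' * an "HO" model adding each individual's mean observed heterozygosity
#'   across all loci.
#' Predictors are deliberately unstandardized here so single-locus and
#' multilocus slopes are on their natural scales.
#'
#' @param x a [genotype_table()].
#' @param year_zero calendar year coded 0 (default 2006).
#' @return object of class `local_effects`: `rows`, a data.frame sorted by
#'   ascending AIC (ties broken alphabetically by model id) with columns
#'   `model`, `aic`, `delta_aic_base`, `delta_aic_ho`, `b0`, `se_b0`,
#'   `b_year`, `se_year`, `b_het`, `se_het`, `het_rate`; plus `n`,
#'   `excluded_monomorphic`.
#' @export
run_local_effects <- function(x, year_zero = 2006) {
  sub <- filter_complete_cases(x, sex = "female", require_traits = TRUE)
  n <- n_individuals(sub)
  if (n > 0 && n < 10 * 4)
    warning("analysis subset smaller than 10 cases per parameter; slopes are indicative only")
  h <- het_matrix(sub)
  mono <- apply(h, 2, function(col) length(unique(col)) < 2L)
  df <- data.frame(litter_size = sub$meta$litter_size,
                   year = sub$meta$year - year_zero)
  fit_row <- function(id, extra = NULL, het_rate = NA_real_) {
    d <- df
    preds <- "year"
    if (!is.null(extra)) {
      d$het <- extra
      preds <- c("year", "het")
    }
    f <- fit_binomial_glm(d, preds, "litter")
    data.frame(model = id, aic = f$aic,
               b0 = f$coefficients[["(Intercept)"]],
               se_b0 = f$se[["(Intercept)"]],
               b_year = f$coefficients[["year"]],
               se_year = f$se[["year"]],
               b_het = if (is.null(extra)) NA_real_ else f$coefficients[["het"]],
               se_het = if (is.null(extra)) NA_real_ else f$se[["het"]],
               het_rate = het_rate, stringsAsFactors = FALSE)
  }
  rows <- list(fit_row("base"),
               fit_row("HO", rowMeans(h), mean(h)))
  for (j in which(!mono))
    rows[[length(rows) + 1L]] <- fit_row(sub$loci[j], h[, j], mean(h[, j]))
  rows <- do.call(rbind, rows)
  rows$delta_aic_base <- rows$aic - rows$aic[rows$model == "base"]
  rows$delta_aic_ho <- rows$aic - rows$aic[rows$model == "HO"]
  rows <- rows[order(rows$aic, rows$model), ]
  rows <- rows[c("model", "aic", "delta_aic_base", "delta_aic_ho",
                 "b0", "se_b0", "b_year", "se_year", "b_het", "se_het",
                 "het_rate")]
  rownames(rows) <- NULL
  structure(list(rows = rows, n = n,
                 excluded_monomorphic = sub$loci[mono],
                 year_zero = year_zero),
            class = "local_effects")
}

#' @export
print.local_effects <- function(x, digits = 3, ...) {
  cat(sprintf("locus-by-locus AIC scan: %d models on %d complete-case females\n",
              nrow(x$rows), x$n))
  if (length(x$excluded_monomorphic))
    cat("  excluded (monomorphic in subset):",
        paste(x$excluded_monomorphic, collapse = ", "), "\n")
  tab <- x$rows
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(utils::head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("  ... (", nrow(tab) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Interpret a local-effects scan
#'
#' Applies the support / effect-size rules: a locus indicates local effects
#' only if its single-locus model is substantially better supported than the
#' multilocus HO model (delta AIC < -4) AND its heterozygosity slope exceeds
#' the multilocus slope in magnitude. Otherwise the pattern is consistent
#' with general, genome-wide effects (inbreeding depression). Loci within
#' |delta AIC| < 2 of the HO model have similar support; loci with slopes
#' opposite in sign to the multilocus slope are flagged (a negative effect
#' of heterozygosity is opposite to the inbreeding-depression prediction
#' when the multilocus effect is positive).
#'
#' @param x a `local_effects` object (or its `rows` data.frame).
#' @return object of class `effects_summary`: `verdict`
#'   (`"local-effects-indicated"` or `"consistent-with-general-effects"`),
#'   `better_than_ho` (loci with delta AIC_HO < -4), `similar_to_ho`
#'   (|delta AIC_HO| < 2), `stronger_than_ho` (loci whose |slope| exceeds
#'   the multilocus slope), `opposite_sign` loci, `ho_slope`, and the
#'   per-locus flag table.
#' @export
classify_effects <- function(x) {
  rows <- if (inherits(x, "local_effects")) x$rows else x
  stopifnot(all(c("base", "HO") %in% rows$model))
  ho_slope <- rows$b_het[rows$model == "HO"]
  loci <- rows[!(rows$model %in% c("base", "HO")), , drop = FALSE]
  if (nrow(loci)) {
    better <- loci$model[loci$delta_aic_ho < -4]
    similar <- loci$model[abs(loci$delta_aic_ho) < 2]
    stronger <- loci$model[abs(loci$b_het) > abs(ho_slope)]
    opposite <- loci$model[sign(loci$b_het) != sign(ho_slope)]
    local <- loci$delta_aic_ho < -4 & abs(loci$b_het) > abs(ho_slope)
    verdict <- if (any(local)) "local-effects-indicated"
    else "consistent-with-general-effects"
    flags <- data.frame(locus = loci$model,
                        b_het = loci$b_het,
                        delta_aic_ho = loci$delta_aic_ho,
                        better_than_ho = loci$delta_aic_ho < -4,
                        stronger_than_ho = abs(loci$b_het) > abs(ho_slope),
                        opposite_sign = sign(loci$b_het) != sign(ho_slope),
                        local_effect = local,
                        stringsAsFactors = FALSE)
  } else {
    # no polymorphic loci: only the base-vs-HO comparison remains
    better <- similar <- stronger <- opposite <- character(0)
    verdict <- "consistent-with-general-effects"
    flags <- data.frame()
  }
  structure(list(verdict = verdict, better_than_ho = better,
                 similar_to_ho = similar, stronger_than_ho = stronger,
                 opposite_sign = opposite, ho_slope = ho_slope,
                 flags = flags),
            class = "effects_summary")
}

#' @export
print.effects_summary <- function(x, ...) {
  cat("verdict:", x$verdict, "\n")
  cat(sprintf("multilocus (HO) slope: %.3f\n", x$ho_slope))
  if (length(x$better_than_ho))
    cat("loci better supported than HO (dAIC < -4):",
        paste(x$better_than_ho, collapse = ", "), "\n")
  if (length(x$similar_to_ho))
    cat("loci with similar support (|dAIC| < 2):",
        paste(x$similar_to_ho, collapse = ", "), "\n")
  if (length(x$opposite_sign))
    cat("loci with slope opposite to the multilocus effect:",
        paste(x$opposite_sign, collapse = ", "), "\n")
  invisible(x)
}

#' Write the local-effects table as TSV
#' @param x a `local_effects` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_local_effects <- function(x, path) {
  tab <- x$rows
  names(tab) <- c("Locus", "AIC", "dAIC_base", "dAIC_HO", "b0", "SE_b0",
                  "b_year", "SE_year", "b_HO", "SE_HO", "H_O")
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, 3)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
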