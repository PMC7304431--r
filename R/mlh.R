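#' Internal relatedness
#'
#' Allele-frequency-weighted homozygosity:
#' \eqn{IR = (2H - \sum f) / (2N - \sum f)} where N is the number of typed
#' polymorphic loci, H the number of those at which the individual is
#' homozygous, and \eqn{\sum f} the summed population frequencies of the 2N
#' allele copies carried. Rare-allele homozygosity is up-weighted because it
#' is more likely to reflect inbred mating. IR reaches 1 for a fully
#' homozygous genotype and goes negative for heterozygote-rich ones.
#' Monomorphic loci are excluded throughout.
#'
#' @param x a [genotype_table()].
#' @param freqs per-locus allele frequencies as returned by
#'   [allele_freqs()]; defaults to pooled full-sample frequencies (the
#'   focal individual included).
#' @return numeric vector, one IR per individual (`NA` where no typed
#'   polymorphic locus is available).
#' @export
internal_relatedness <- function(x, freqs = NULL) {
  if (is.null(freqs)) freqs <- allele_freqs(x)
  poly <- vapply(freqs, function(f) !is.null(f) && length(f) > 1L, logical(1))
  vapply(seq_len(nrow(x$a1)), function(i) {
    H <- 0L; N <- 0L; sumf <- 0
    for (j in which(poly)) {
      u <- x$a1[i, j]; v <- x$a2[i, j]
      if (is.na(u)) next
      f <- freqs[[j]]
      if (is.na(f[u]) || is.na(f[v]))
        stop(sprintf("no frequency for allele carried at locus '%s'",
                     x$loci[j]))
      N <- N + 1L
      if (u == v) H <- H + 1L
      sumf <- sumf + f[[u]] + f[[v]]
    }
    den <- 2 * N - sumf
    if (N == 0L || den == 0) NA_real_ else (2 * H - sumf) / den
  }, numeric(1))
}

#' Standardized multilocus heterozygosity
#'
#' Ratio of an individual's heterozygous typed loci to the sum, over the
#' same loci, of the sample mean observed heterozygosity — so an individual
#' typed at every locus with typical heterozygosity scores 1, and
#' missingness is handled by standardizing only over the loci actually
#' typed.
#'
#' @inheritParams internal_relatedness
#' @param locus_ho optional per-locus mean observed heterozygosity (named by
#'   locus); computed from `x` when omitted.
#' @return numeric vector of sMLH values (`NA` when every typed locus has
#'   zero mean heterozygosity).
#' @export
smlh <- function(x, locus_ho = NULL) {
  het <- het_matrix(x)
  if (is.null(locus_ho)) locus_ho <- colMeans(het, na.rm = TRUE)
  vapply(seq_len(nrow(het)), function(i) {
    typed <- !is.na(het[i, ])
    denom <- sum(locus_ho[typed])
    if (!any(typed) || denom == 0) NA_real_
    else sum(het[i, typed]) / denom
  }, numeric(1))
}

#' Heterozygosity by loci
#'
#' \eqn{HL = \sum E_{hom} / (\sum E_{hom} + \sum E_{het})}: loci are
#' weighted by their expected heterozygosity, summed over the individual's
#' homozygous vs heterozygous typed loci. HL is 0 for a fully heterozygous
#' genotype and 1 for a fully homozygous one.
#'
#' @inheritParams internal_relatedness
#' @param locus_uhe optional per-locus unbiased expected heterozygosity;
#'   computed from `x` when omitted.
#' @return numeric vector of HL values in `[0, 1]`.
#' @export
hl <- function(x, locus_uhe = NULL) {
  het <- het_matrix(x)
  if (is.null(locus_uhe)) locus_uhe <- locus_summary_uhe(x)
  vapply(seq_len(nrow(het)), function(i) {
    typed <- !is.na(het[i, ])
    e <- locus_uhe[typed]
    h <- het[i, typed]
    tot <- sum(e)
    if (!any(typed) || tot == 0) NA_real_ else sum(e[h == 0]) / tot
  }, numeric(1))
}

## uhe only, without the HWE machinery of locus_summary()
locus_summary_uhe <- function(x) {
  vapply(seq_along(x$loci), function(j) {
    a1 <- x$a1[, j]; a2 <- x$a2[, j]
    typed <- !is.na(a1)
    n <- sum(typed)
    if (n == 0L) return(NA_real_)
    p <- table(c(a1[typed], a2[typed])) / (2 * n)
    (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  }, numeric(1))
}

#' Per-individual multilocus heterozygosity records
#'
#' Computes IR, sMLH and HL for every individual together with the fraction
#' of loci typed.
#'
#' @param x a [genotype_table()].
#' @param freqs pooled allele frequencies (defaults to [allele_freqs()] on
#'   the full table, focal individuals included).
#' @return data.frame: `id`, `sex`, `year`, `prop_typed`, `ir`, `smlh`,
#'   `hl`.
#' @export
mlh <- function(x, freqs = NULL) {
  data.frame(id = x$meta$id, sex = x$meta$sex, year = x$meta$year,
             prop_typed = rowMeans(!is.na(x$a1)),
             ir = internal_relatedness(x, freqs),
             smlh = smlh(x),
             hl = hl(x),
             stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations between heterozygosity indices
#'
#' @param records data.frame from [mlh()] (uses the `ir`, `smlh`, `hl`
#'   columns), or any data.frame of numeric index columns.
#' @return symmetric correlation matrix (pairwise-complete observations);
#'   zero-variance indices give `NA` entries.
#' @export
mlh_correlations <- function(records) {
  cols <- intersect(c("ir", "smlh", "hl"), names(records))
  if (!length(cols)) cols <- names(records)[vapply(records, is.numeric, logical(1))]
  m <- as.matrix(records[cols])
  stopifnot(nrow(m) >= 3L)
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

#' Linear trend of an index over calendar years
#'
#' Ordinary least squares of a per-individual index on raw (unshifted)
#' calendar year with t-based inference, as used to test whether inbreeding
#' accumulates over a sampling period. A response with zero variance is
#' reported as slope 0 with p = 1 (no trend).
#'
#' @param values per-individual index values.
#' @param years calendar years (same length).
#' @return object of class `trend_fit`: slope, slope SE, intercept,
#'   intercept SE, two-sided p-values, n.
#' @export
index_year_trend <- function(values, years) {
  keep <- !is.na(values) & !is.na(years)
  values <- values[keep]; years <- years[keep]
  stopifnot(length(values) >= 3L)
  if (length(unique(years)) < 2L) {
    warning("single sampling year: slope undefined")
    return(structure(list(slope = NA_real_, slope_se = NA_real_,
                          intercept = mean(values), intercept_se = NA_real_,
                          p_slope = NA_real_, p_intercept = NA_real_,
                          n = length(values)), class = "trend_fit"))
  }
  if (stats::var(values) == 0) {
    return(structure(list(slope = 0, slope_se = 0,
                          intercept = values[1L], intercept_se = 0,
                          p_slope = 1, p_intercept = NA_real_,
                          n = length(values)), class = "trend_fit"))
  }
  fit <- stats::lm(values ~ years)
  cf <- summary(fit)$coefficients
  structure(list(slope = cf["years", 1], slope_se = cf["years", 2],
                 intercept = cf["(Intercept)", 1],
                 intercept_se = cf["(Intercept)", 2],
                 p_slope = cf["years", 4], p_intercept = cf["(Intercept)", 4],
                 n = length(values)), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("year trend: slope %.4f +/- %.4f SE (p = %.3g), intercept %.3f +/- %.3f, n = %d\n",
              x$slope, x$slope_se, x$p_slope, x$intercept, x$intercept_se, x$n))
  invisible(x)
}

#' Write per-individual MLH records as TSV
#' @param records data.frame from [mlh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mlh <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
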