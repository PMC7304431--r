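#' Per-locus diversity summary
#'
#' For each locus: number of typed individuals, allele count Na, observed
#' heterozygosity H_O, unbiased expected heterozygosity
#' \eqn{uH_E = \frac{2n}{2n-1}(1 - \sum_a p_a^2)}, and a Hardy-Weinberg
#' exact-test p-value (NA for monomorphic loci).
#'
#' @param x a [genotype_table()].
#' @param n_mc Monte-Carlo permutations for the HWE test at loci with more
#'   than three alleles (enumeration is used otherwise).
#' @param seed RNG seed for the Monte-Carlo HWE tests.
#' @return data.frame with one row per locus: `locus`, `n_typed`, `na`,
#'   `ho`, `uhe`, `hwe_p`, `monomorphic`. Method metadata (exact-test family
#'   and iteration count) is recorded in the `"hwe_method"` attribute.
#' @export
locus_summary <- function(x, n_mc = 10000L, seed = 1L) {
  loci <- x$loci
  out <- data.frame(locus = loci, n_typed = NA_integer_, na = NA_integer_,
                    ho = NA_real_, uhe = NA_real_, hwe_p = NA_real_,
                    monomorphic = NA, stringsAsFactors = FALSE)
  for (j in seq_along(loci)) {
    a1 <- x$a1[, j]; a2 <- x$a2[, j]
    typed <- !is.na(a1)
    n <- sum(typed)
    out$n_typed[j] <- n
    if (n == 0L) next  # row stays flagged undefined
    a1 <- a1[typed]; a2 <- a2[typed]
    alleles <- c(a1, a2)
    p <- table(alleles) / (2 * n)
    out$na[j] <- length(p)
    out$ho[j] <- mean(a1 != a2)
    out$uhe[j] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    out$monomorphic[j] <- length(p) == 1L
    if (length(p) > 1L)
      out$hwe_p[j] <- hwe_exact_test(a1, a2, n_mc = n_mc,
                                     seed = seed + j)$p.value
  }
  attr(out, "hwe_method") <-
    sprintf("conditional exact test (complete enumeration <=3 alleles, %d Monte-Carlo permutations otherwise)", n_mc)
  out
}

#' Multi-allelic Hardy-Weinberg exact test
#'
#' Conditional exact test of Hardy-Weinberg proportions. Given the observed
#' allele counts, the probability of a genotype configuration is proportional
#' to \eqn{2^H / \prod_g n_g!} (H = number of heterozygotes); the p-value is
#' the total conditional probability of configurations no more probable than
#' the observed one. Configurations are enumerated completely for loci with
#' at most three alleles; beyond that the null distribution is sampled by
#' permuting the vector of 2n gene copies and re-pairing, with the add-one
#' correction `p = (1 + #{perm <= obs}) / (n_mc + 1)`.
#'
#' @param a1,a2 allele vectors (one entry per typed individual).
#' @param n_mc number of Monte-Carlo permutations.
#' @param seed RNG seed (Monte-Carlo path only).
#' @param method `"auto"` (enumerate up to 3 alleles), `"enum"`, or `"mc"`.
#' @return list with `p.value`, `method`, `n_alleles`.
#' @export
hwe_exact_test <- function(a1, a2, n_mc = 10000L, seed = NULL,
                           method = c("auto", "enum", "mc")) {
  method <- match.arg(method)
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- as.character(a1[keep]); a2 <- as.character(a2[keep])
  stopifnot(length(a1) == length(a2), length(a1) > 0L)
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2L) return(list(p.value = NA_real_, method = "monomorphic",
                          n_alleles = k))
  if (method == "auto") method <- if (k <= 3L) "enum" else "mc"
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  obs_lw <- .hwe_logweight(i1, i2, k)
  if (method == "enum") {
    tab <- .hwe_enumerate(tabulate(c(i1, i2), nbins = k))
    tol <- 1e-9
    p <- sum(tab$prob[tab$logw <= obs_lw + tol])
    return(list(p.value = p, method = "enumeration", n_alleles = k))
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- c(i1, i2)
  n <- length(i1)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    perm <- sample(pool)
    lw <- .hwe_logweight(perm[seq_len(n)], perm[n + seq_len(n)], k)
    if (lw <= obs_lw + 1e-9) hits <- hits + 1L
  }
  list(p.value = (1 + hits) / (n_mc + 1), method = "monte-carlo",
       n_alleles = k, n_mc = n_mc)
}

## log conditional weight of a genotype configuration: H*log2 - sum(lfactorial(n_g))
.hwe_logweight <- function(i1, i2, k) {
  g <- pmin(i1, i2) + k * pmax(i1, i2)  # unordered genotype code
  ng <- table(g)
  sum(i1 != i2) * log(2) - sum(lfactorial(as.numeric(ng)))
}

## enumerate all genotype tables consistent with allele counts (k <= 3)
.hwe_enumerate <- function(cnt) {
  k <- length(cnt)
  logw <- numeric(0)
  add <- function(het, hom) {
    h <- sum(het)
    logw <<- c(logw, h * log(2) - sum(lfactorial(c(het, hom))))
  }
  if (k == 2L) {
    for (n12 in seq(cnt[1] %% 2L, min(cnt), by = 2L)) {
      hom <- c((cnt[1] - n12) / 2, (cnt[2] - n12) / 2)
      add(n12, hom)
    }
  } else if (k == 3L) {
    for (n12 in 0:min(cnt[1], cnt[2]))
      for (n13 in 0:min(cnt[1] - n12, cnt[3]))
        for (n23 in 0:min(cnt[2] - n12, cnt[3] - n13)) {
          hom2 <- cnt - c(n12 + n13, n12 + n23, n13 + n23)
          if (any(hom2 < 0) || any(hom2 %% 2L != 0L)) next
          add(c(n12, n13, n23), hom2 / 2)
        }
  } else stop("enumeration supports at most 3 alleles")
  w <- exp(logw - max(logw))
  data.frame(logw = logw, prob = w / sum(w))
}

#' Nei F_IS per locus and cohort
#'
#' Within-cohort inbreeding coefficient \eqn{F_{IS} = 1 - H_O/H_S}, with the
#' small-sample-corrected gene diversity
#' \eqn{H_S = \frac{n}{n-1}\left(1 - \sum_a \bar p_a^2 - H_O/(2n)\right)}
#' (Nei & Chesser correction). Monomorphic locus-cohorts are `NA` and are
#' excluded from the unweighted cohort mean.
#'
#' @param x a [genotype_table()].
#' @param by cohort assignment: a metadata column name (default `"year"`) or
#'   a vector with one entry per individual.
#' @return list of class `fis_series`: `fis` (loci x cohorts matrix),
#'   `cohort_mean` (named vector), `n` (typed counts matrix).
#' @export
nei_fis <- function(x, by = "year") {
  grp <- if (is.character(by) && length(by) == 1L) x$meta[[by]] else by
  stopifnot(length(grp) == nrow(x$a1))
  cohorts <- sort(unique(grp))
  L <- length(x$loci)
  fis <- matrix(NA_real_, L, length(cohorts),
                dimnames = list(x$loci, as.character(cohorts)))
  ncal <- fis
  for (ci in seq_along(cohorts)) {
    idx <- which(grp == cohorts[ci])
    for (j in seq_len(L)) {
      a1 <- x$a1[idx, j]; a2 <- x$a2[idx, j]
      typed <- !is.na(a1)
      n <- sum(typed)
      ncal[j, ci] <- n
      if (n < 2L) next
      a1 <- a1[typed]; a2 <- a2[typed]
      p <- table(c(a1, a2)) / (2 * n)
      if (length(p) < 2L) next  # monomorphic in this cohort
      ho <- mean(a1 != a2)
      hs <- (n / (n - 1)) * (1 - sum(p^2) - ho / (2 * n))
      if (hs <= 0) next
      fis[j, ci] <- 1 - ho / hs
    }
  }
  structure(list(fis = fis,
                 cohort_mean = colMeans(fis, na.rm = TRUE),
                 n = ncal),
            class = "fis_series")
}

#' @export
print.fis_series <- function(x, ...) {
  cat("F_IS by cohort (unweighted mean over defined loci):\n")
  print(round(x$cohort_mean, 4))
  invisible(x)
}

#' Brookfield null-allele frequency estimate
#'
#' Estimator 1 of Brookfield (1996): from a heterozygote deficit,
#' \eqn{r = (H_E - H_O) / (1 + H_E)}, clamped to 0 when negative. This form
#' assumes null homozygotes appear as missing data rather than as scored
#' homozygotes.
#'
#' @param ho,uhe observed and (unbiased) expected heterozygosity, vectors
#'   recycled to common length; values in `[0, 1]`.
#' @return estimated null-allele frequency, same length as the inputs.
#' @export
brookfield_null <- function(ho, uhe) {
  stopifnot(all(ho >= 0 & ho <= 1, na.rm = TRUE),
            all(uhe >= 0 & uhe <= 1, na.rm = TRUE))
  pmax(0, (uhe - ho) / (1 + uhe))
}

#' Null-allele frequencies per cohort and locus
#'
#' Applies [brookfield_null()] within cohorts, using per-cohort allele
#' frequencies and per-cohort H_O / unbiased H_E. A locus monomorphic within
#' a cohort yields `NA` for that cell.
#'
#' @param x a [genotype_table()].
#' @param by cohort column name (default `"year"`) or assignment vector.
#' @return data.frame: `locus`, then one numeric column per cohort.
#' @export
null_allele_table <- function(x, by = "year") {
  grp <- if (is.character(by) && length(by) == 1L) x$meta[[by]] else by
  cohorts <- sort(unique(grp))
  out <- data.frame(locus = x$loci, stringsAsFactors = FALSE)
  for (co in cohorts) {
    idx <- which(grp == co)
    vals <- rep(NA_real_, length(x$loci))
    for (j in seq_along(x$loci)) {
      a1 <- x$a1[idx, j]; a2 <- x$a2[idx, j]
      typed <- !is.na(a1)
      n <- sum(typed)
      if (n < 2L) next
      a1 <- a1[typed]; a2 <- a2[typed]
      p <- table(c(a1, a2)) / (2 * n)
      if (length(p) < 2L) next
      ho <- mean(a1 != a2)
      uhe <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      vals[j] <- brookfield_null(ho, min(uhe, 1))
    }
    out[[as.character(co)]] <- vals
  }
  out
}

#' Write a locus summary TSV
#'
#' Diversity-table export: Locus, N, Na, H_O, H_E, p-value, then one
#' null-allele-frequency column per cohort.
#'
#' @param summary result of [locus_summary()].
#' @param nulls result of [null_allele_table()] (optional).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_locus_summary <- function(summary, path, nulls = NULL) {
  out <- data.frame(Locus = summary$locus, N = summary$n_typed,
                    Na = summary$na, H_O = round(summary$ho, 3),
                    H_E = round(summary$uhe, 3),
                    p_value = round(summary$hwe_p, 3),
                    stringsAsFactors = FALSE)
  if (!is.null(nulls)) {
    stopifnot(identical(nulls$locus, summary$locus))
    for (nm in setdiff(names(nulls), "locus"))
      out[[paste0("null_", nm)]] <- round(nulls[[nm]], 3)
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
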