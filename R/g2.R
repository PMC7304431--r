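#' Individual-by-locus heterozygosity matrix
#'
#' @param x a [genotype_table()].
#' @return numeric matrix (individuals x loci): 1 heterozygous, 0
#'   homozygous, `NA` missing.
#' @export
het_matrix <- function(x) {
  h <- (x$a1 != x$a2) * 1
  dimnames(h) <- list(x$meta$id, x$loci)
  h
}

#' g2 identity-disequilibrium point estimate
#'
#' Excess double heterozygosity across locus pairs within individuals.
#' Over ordered locus pairs (i, j), i != j, each restricted to the
#' individuals typed at both (pairwise-complete, N_ij of them):
#' \deqn{num_{ij} = \frac{1}{N_{ij}} \sum_k h_{ki} h_{kj}, \quad
#'       den_{ij} = \frac{1}{N_{ij}(N_{ij}-1)} \sum_{k \ne l} h_{ki} h_{lj}}
#' and \eqn{\hat g_2 = \sum num_{ij} / \sum den_{ij} - 1}. Nonzero g2
#' indicates variance in inbreeding among individuals — the precondition
#' for reading a heterozygosity-fitness correlation as inbreeding
#' depression. Under a multiplicative model where an individual with
#' inbreeding coefficient f is heterozygous at locus l with probability
#' \eqn{h_l (1 - f)}, the estimand is \eqn{Var(f) / (1 - E[f])^2}.
#'
#' @param h a 0/1/NA heterozygosity matrix ([het_matrix()]) or a
#'   [genotype_table()].
#' @return the g2 estimate (scalar). Locus pairs with fewer than two
#'   jointly typed individuals are dropped with a warning; if all pairs are
#'   dropped (or the denominator vanishes) the estimate is `NA`.
#' @export
g2_point <- function(h) {
  h <- .as_het(h)
  stopifnot(ncol(h) >= 2L, nrow(h) >= 3L)
  M <- (!is.na(h)) * 1
  H0 <- h; H0[is.na(h)] <- 0
  Nij <- crossprod(M)              # individuals typed at both loci
  S <- crossprod(H0)               # sum_k h_ki h_kj over jointly typed
  A <- crossprod(H0, M)            # A[i,j] = sum_k h_ki m_kj
  off <- row(Nij) != col(Nij)
  ok <- off & Nij >= 2L
  if (any(off & !ok))
    warning(sum(off & !ok) / 2, " locus pair(s) with < 2 jointly typed individuals dropped")
  if (!any(ok)) return(NA_real_)
  num <- S / Nij
  den <- (A * t(A) - S) / (Nij * (Nij - 1))
  dsum <- sum(den[ok])
  if (dsum == 0) return(NA_real_)
  sum(num[ok]) / dsum - 1
}

.as_het <- function(h) {
  if (inherits(h, "genotype_table")) h <- het_matrix(h)
  as.matrix(h)
}

#' g2 with bootstrap SE and permutation p-value
#'
#' Point estimate via [g2_point()]; precision from `n_boot` bootstrap
#' resamples of individuals (with replacement); significance from `n_perm`
#' permutations in which every locus column is shuffled independently
#' across individuals — destroying between-locus association while
#' preserving each locus's heterozygosity rate and missingness pattern.
#' (Permuting whole individuals would preserve the very association being
#' tested.) The p-value uses the add-one correction
#' `p = (1 + #{g2_perm >= g2_obs}) / (n_perm + 1)` and so is never 0.
#'
#' @inheritParams g2_point
#' @param n_iter default iteration count for both resampling schemes.
#' @param seed RNG seed (recorded in the result).
#' @param n_boot,n_perm override the bootstrap / permutation counts
#'   separately (0 disables that component).
#' @return object of class `g2_test`: `g2`, `se`, `p`, `n_boot`, `n_perm`,
#'   `seed`, `n_ind`, `n_loci`, plus the bootstrap and permutation draws.
#' @export
g2_test <- function(h, n_iter = 1000L, seed = NULL,
                    n_boot = n_iter, n_perm = n_iter) {
  h <- .as_het(h)
  if (max(n_boot, n_perm) < 100L)
    warning("fewer than 100 iterations: SE and p-value tails are unstable")
  if (!is.null(seed)) set.seed(seed)
  obs <- g2_point(h)
  N <- nrow(h)
  boot <- if (n_boot > 0L) vapply(seq_len(n_boot), function(b) {
    suppressWarnings(g2_point(h[sample.int(N, N, replace = TRUE), , drop = FALSE]))
  }, numeric(1)) else numeric(0)
  perm <- if (n_perm > 0L) vapply(seq_len(n_perm), function(b) {
    hp <- apply(h, 2, sample)
    suppressWarnings(g2_point(hp))
  }, numeric(1)) else numeric(0)
  p <- if (n_perm > 0L)
    (1 + sum(perm >= obs, na.rm = TRUE)) / (n_perm + 1)
  else NA_real_
  structure(list(g2 = obs,
                 se = if (n_boot > 0L) stats::sd(boot, na.rm = TRUE) else NA_real_,
                 p = p, n_boot = n_boot, n_perm = n_perm, seed = seed,
                 n_ind = N, n_loci = ncol(h),
                 boot = boot, perm = perm),
            class = "g2_test")
}

#' @export
print.g2_test <- function(x, ...) {
  cat(sprintf("g2 = %.4f (bootstrap SE = %.4f, permutation p = %.4g)\n",
              x$g2, x$se, x$p))
  cat(sprintf("  %d individuals x %d loci; %d bootstrap, %d permutation iterations; seed %s\n",
              x$n_ind, x$n_loci, x$n_boot, x$n_perm,
              if (is.null(x$seed)) "none" else x$seed))
  cat("  missing data: pairwise-complete per locus pair\n")
  invisible(x)
}
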