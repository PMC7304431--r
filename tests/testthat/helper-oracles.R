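# Independent oracles and small fixture builders used across the suite.

## quadruple-loop g2: the literal pairwise-complete definition, no vectorization
g2_brute <- function(h) {
  L <- ncol(h)
  num <- 0; den <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    ok <- which(!is.na(h[, i]) & !is.na(h[, j]))
    Nij <- length(ok)
    if (Nij < 2) next
    s_num <- 0
    for (k in ok) s_num <- s_num + h[k, i] * h[k, j]
    s_den <- 0
    for (k in ok) for (l in ok) if (k != l) s_den <- s_den + h[k, i] * h[l, j]
    num <- num + s_num / Nij
    den <- den + s_den / (Nij * (Nij - 1))
  }
  num / den - 1
}

## independent IRLS for a binomial logit model with y events out of `trials`
irls_fit <- function(X, y, trials) {
  beta <- rep(0, ncol(X))
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- trials * mu * (1 - mu)
    z <- eta + (y / trials - mu) / (mu * (1 - mu))
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- trials * mu * (1 - mu)
  list(coefficients = beta, se = sqrt(diag(solve(t(X * w) %*% X))))
}

## random 0/1/NA heterozygosity matrix
rand_het <- function(n, L, miss = 0.1) {
  h <- matrix(rbinom(n * L, 1, runif(L, 0.2, 0.8)[rep(seq_len(L), each = n)]),
              n, L)
  if (miss > 0) h[matrix(runif(n * L) < miss, n, L)] <- NA
  h
}

## tiny genotype table from an allele-pair list: calls[[locus]][[ind]] = c(a, b) or NA
make_gt <- function(calls, sex = NULL, year = NULL, age = NULL,
                    litter = NULL) {
  L <- length(calls)
  n <- length(calls[[1]])
  a1 <- a2 <- matrix(NA_character_, n, L,
                     dimnames = list(NULL, names(calls)))
  for (j in seq_len(L)) for (i in seq_len(n)) {
    cl <- calls[[j]][[i]]
    if (length(cl) == 2L && !any(is.na(cl))) {
      a1[i, j] <- cl[1]; a2[i, j] <- cl[2]
    }
  }
  meta <- data.frame(id = paste0("i", seq_len(n)),
                     sex = if (is.null(sex)) rep("female", n) else sex,
                     year = if (is.null(year)) rep(2006L, n) else year,
                     age = if (is.null(age)) rep(2, n) else age,
                     litter_size = if (is.null(litter)) rep(NA_integer_, n) else litter,
                     stringsAsFactors = FALSE)
  genotype_table(meta, a1, a2)
}

## write a genotype CSV from a character matrix of rows (for reader tests)
write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
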