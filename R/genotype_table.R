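#' Codominant genotype table with individual metadata
#'
#' A `genotype_table` bundles unordered diploid allele calls at a set of
#' microsatellite loci with per-individual metadata (sex, calendar year of
#' capture, age, litter size). Allele labels are opaque strings; a call is
#' either fully present (both alleles) or wholly missing.
#'
#' @param meta data.frame with columns `id` (unique, character), `sex`
#'   ("female"/"male" or `NA`), `year` (integer calendar year), `age`
#'   (positive numeric or `NA`) and `litter_size` (integer 0--4 or `NA`).
#' @param a1,a2 character matrices (individuals x loci) of allele labels;
#'   `NA` marks a missing call and must occur in both matrices at once.
#'   Column names are the locus names; both matrices must agree.
#'
#' @return An object of class `genotype_table`: a list with elements `meta`,
#'   `a1`, `a2` and `loci`.
#' @seealso [read_genotypes()], [filter_complete_cases()], [allele_freqs()]
#' @export
genotype_table <- function(meta, a1, a2) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"
  storage.mode(a2) <- "character"
  required <- c("id", "sex", "year", "age", "litter_size")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id))
    stop("duplicate individual id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices differ in dimension")
  if (nrow(a1) != nrow(meta))
    stop("allele matrices and metadata disagree on the number of individuals")
  loci <- colnames(a1)
  if (is.null(loci) || anyDuplicated(loci))
    stop("locus names must be present and unique")
  if (!identical(loci, colnames(a2)))
    stop("allele matrices disagree on locus names")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("half-call (one allele missing) for individual '%s' at locus '%s'",
                 meta$id[w[1L]], loci[w[2L]]))
  }
  bad_litter <- !is.na(meta$litter_size) & !(meta$litter_size %in% 0:4)
  if (any(bad_litter))
    stop("litter_size outside 0..4 for individual(s): ",
         paste(meta$id[bad_litter], collapse = ", "))
  bad_sex <- !is.na(meta$sex) & !(meta$sex %in% c("female", "male"))
  if (any(bad_sex))
    stop("sex must be 'female' or 'male' (or NA)")
  rownames(a1) <- rownames(a2) <- meta$id
  structure(list(meta = meta, a1 = a1, a2 = a2, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing calls)\n",
              nrow(x$a1), length(x$loci), 100 * miss))
  cat(sprintf("  years: %s\n",
              paste(sort(unique(x$meta$year)), collapse = ", ")))
  nf <- sum(x$meta$sex == "female", na.rm = TRUE)
  cat(sprintf("  %d females, %d males; litter size known for %d\n",
              nf, sum(x$meta$sex == "male", na.rm = TRUE),
              sum(!is.na(x$meta$litter_size))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$a1)

#' Number of individuals / loci in a genotype table
#' @param x a [genotype_table()].
#' @return integer count.
#' @export
n_individuals <- function(x) nrow(x$a1)

#' @rdname n_individuals
#' @export
n_loci <- function(x) length(x$loci)

## internal: subset rows (individuals), keeping the class invariants
subset_individuals <- function(x, keep) {
  genotype_table(x$meta[keep, , drop = FALSE],
                 x$a1[keep, , drop = FALSE],
                 x$a2[keep, , drop = FALSE])
}

#' Read a two-column-per-locus genotype CSV
#'
#' Reads a GenAlEx-style export: a header row, the metadata columns `id`,
#' `sex`, `year`, `age`, `litter_size` (matched case-insensitively), then two
#' columns per locus. In the `"interleaved"` layout the two allele columns of
#' each locus are adjacent (the second may carry any suffixed header, e.g.
#' `Loc` and `Loc.1` or `Loc_a`/`Loc_b`); in the `"blocked"` layout all first
#' alleles precede all second alleles.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param missing_codes cell values normalized to a missing call.
#' @param layout locus column layout, `"interleaved"` (default) or
#'   `"blocked"`.
#' @return A [genotype_table()]. A call with exactly one allele coded missing
#'   is a hard error naming the individual and locus.
#' @export
read_genotypes <- function(path,
                           missing_codes = c("", "0", "NA", "na"),
                           layout = c("interleaved", "blocked")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL,
                         strip.white = TRUE)
  hdr <- names(raw)
  meta_names <- c("id", "sex", "year", "age", "litter_size")
  meta_idx <- match(meta_names, tolower(hdr))
  if (any(is.na(meta_idx)))
    stop("missing metadata column(s): ",
         paste(meta_names[is.na(meta_idx)], collapse = ", "))
  locus_idx <- setdiff(seq_along(hdr), meta_idx)
  if (length(locus_idx) %% 2L != 0L)
    stop("odd number of locus columns; expected two per locus")
  if (layout == "interleaved") {
    first <- locus_idx[seq(1L, length(locus_idx), by = 2L)]
    second <- locus_idx[seq(2L, length(locus_idx), by = 2L)]
  } else {
    half <- length(locus_idx) / 2L
    first <- locus_idx[seq_len(half)]
    second <- locus_idx[half + seq_len(half)]
  }
  ## strip an explicit pair suffix (".1", "_a", "_A") but leave bare names alone
  loci <- sub("[._](1|a|A)$", "", hdr[first])
  a1 <- as.matrix(raw[first]); a2 <- as.matrix(raw[second])
  colnames(a1) <- colnames(a2) <- loci
  a1[a1 %in% missing_codes] <- NA_character_
  a2[a2 %in% missing_codes] <- NA_character_
  to_num <- function(v) suppressWarnings(as.numeric(v))
  meta <- data.frame(id = raw[[meta_idx[1L]]],
                     sex = tolower(raw[[meta_idx[2L]]]),
                     year = as.integer(to_num(raw[[meta_idx[3L]]])),
                     age = to_num(raw[[meta_idx[4L]]]),
                     litter_size = as.integer(to_num(raw[[meta_idx[5L]]])),
                     stringsAsFactors = FALSE)
  meta$sex[meta$sex %in% c(missing_codes, "")] <- NA_character_
  genotype_table(meta, a1, a2)
}

#' Write a genotype table as a two-column-per-locus CSV
#'
#' Inverse of [read_genotypes()] (interleaved layout; missing calls become
#' empty cells). Reading the written file back yields an identical table.
#'
#' @param x a [genotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(x, path) {
  L <- length(x$loci)
  geno <- matrix("", nrow = nrow(x$a1), ncol = 2L * L)
  geno[, seq(1L, 2L * L, by = 2L)] <- ifelse(is.na(x$a1), "", x$a1)
  geno[, seq(2L, 2L * L, by = 2L)] <- ifelse(is.na(x$a2), "", x$a2)
  hdr <- character(2L * L)
  hdr[seq(1L, 2L * L, by = 2L)] <- x$loci
  hdr[seq(2L, 2L * L, by = 2L)] <- paste0(x$loci, ".1")
  m <- x$meta
  out <- cbind(data.frame(id = m$id, sex = ifelse(is.na(m$sex), "", m$sex),
                          year = m$year, age = m$age,
                          litter_size = m$litter_size,
                          stringsAsFactors = FALSE),
               as.data.frame(geno, stringsAsFactors = FALSE))
  names(out) <- c("id", "sex", "year", "age", "litter_size", hdr)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Complete-case filtering
#'
#' Retains individuals with no missing genotype calls at any locus,
#' optionally restricted by sex and to individuals with known litter size.
#' Used to form the analysis subset of the locus-by-locus local-effects
#' models, which (like any standard multiple regression) require complete
#' data.
#'
#' @param x a [genotype_table()].
#' @param sex optional `"female"` or `"male"` restriction.
#' @param require_traits if `TRUE`, also require a known `litter_size`.
#' @return the filtered [genotype_table()]; a warning (not an error) if no
#'   individual survives.
#' @export
filter_complete_cases <- function(x, sex = NULL, require_traits = FALSE) {
  keep <- rowSums(is.na(x$a1)) == 0L
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("female", "male"))
    keep <- keep & !is.na(x$meta$sex) & x$meta$sex == sex
  }
  if (require_traits) keep <- keep & !is.na(x$meta$litter_size)
  if (!any(keep)) warning("complete-case filter retained no individuals")
  subset_individuals(x, keep)
}

#' Allele frequencies by gene counting
#'
#' Relative allele frequencies per locus, pooled over all non-missing calls
#' (both sexes, all years) by default, or within cohorts given by `by`.
#' Pooling across the whole sample is the default because all available
#' individuals are used to estimate frequencies for the internal-relatedness
#' index; per-cohort frequencies feed the per-year null-allele estimates.
#'
#' @param x a [genotype_table()].
#' @param by optional grouping: a metadata column name (e.g. `"year"`) or a
#'   vector with one entry per individual.
#' @return If `by` is `NULL`, a named list (one element per locus) of named
#'   frequency vectors summing to 1; a locus with zero non-missing calls gets
#'   `NULL` and is reported in the `"undefined_loci"` attribute. Otherwise a
#'   list of such lists, one per group.
#' @export
allele_freqs <- function(x, by = NULL) {
  if (is.null(by)) return(.freqs_one(x$a1, x$a2, x$loci))
  grp <- if (is.character(by) && length(by) == 1L) x$meta[[by]] else by
  stopifnot(length(grp) == nrow(x$a1))
  out <- lapply(split(seq_along(grp), grp), function(idx)
    .freqs_one(x$a1[idx, , drop = FALSE], x$a2[idx, , drop = FALSE], x$loci))
  out
}

.freqs_one <- function(a1, a2, loci) {
  res <- vector("list", length(loci))
  names(res) <- loci
  undef <- character(0)
  for (j in seq_along(loci)) {
    alleles <- c(a1[, j], a2[, j])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) {
      undef <- c(undef, loci[j])
      next
    }
    tab <- table(alleles)
    res[[j]] <- as.numeric(tab) / sum(tab)
    names(res[[j]]) <- names(tab)
  }
  attr(res, "undefined_loci") <- undef
  res
}
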