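# Per-locus allele and genotype counting: the substrate for the
# Hardy-Weinberg and Ewens-Watterson tests.

#' Per-locus allele counts and frequencies
#'
#' Counts alleles at one locus. Individuals untyped at either allele of this
#' locus are excluded (per-locus deletion); the number excluded is reported.
#'
#' @param dataset A `pop_dataset`.
#' @param locus Locus name.
#' @return An `allele_freq_table`: list with `locus`, `counts` (named integer,
#'   sorted by allele name), `n_gametes` (2 x included individuals),
#'   `n_individuals`, `n_excluded`, `freqs` (named numeric summing to 1) and
#'   `k` (number of distinct alleles).
#' @export
count_alleles <- function(dataset, locus) {
  stopifnot(inherits(dataset, "pop_dataset"))
  if (!locus %in% dataset$loci) {
    stop(sprintf("locus '%s' not in dataset", locus), call. = FALSE)
  }
  j <- match(locus, dataset$loci)
  a1 <- dataset$allele1[, j]
  a2 <- dataset$allele2[, j]
  complete <- !is.na(a1) & !is.na(a2)
  if (!any(complete)) {
    stop(sprintf("no typed data at locus %s", locus), call. = FALSE)
  }
  alleles <- c(a1[complete], a2[complete])
  counts <- table(alleles)
  counts <- counts[order(names(counts))]
  counts_int <- as.integer(counts)
  names(counts_int) <- names(counts)
  n_gametes <- sum(counts_int)
  structure(
    list(locus = locus,
         counts = counts_int,
         n_gametes = n_gametes,
         n_individuals = sum(complete),
         n_excluded = sum(!complete),
         freqs = counts_int / n_gametes,
         k = length(counts_int)),
    class = "allele_freq_table"
  )
}

#' Per-locus genotype counts
#'
#' Counts unordered genotypes (allele pairs) at one locus, with the same
#' per-locus exclusion of untyped individuals as [count_alleles()]. Genotype
#' identity is order-insensitive: `A/a` and `a/A` are one class.
#'
#' @inheritParams count_alleles
#' @return A `genotype_count_table`: list with `locus`, `counts` (named
#'   integer; names are `allele1/allele2` with the pair sorted), `alleles`
#'   (sorted distinct alleles), `n_individuals` and `n_excluded`.
#' @export
genotype_counts <- function(dataset, locus) {
  stopifnot(inherits(dataset, "pop_dataset"))
  if (!locus %in% dataset$loci) {
    stop(sprintf("locus '%s' not in dataset", locus), call. = FALSE)
  }
  j <- match(locus, dataset$loci)
  a1 <- dataset$allele1[, j]
  a2 <- dataset$allele2[, j]
  complete <- !is.na(a1) & !is.na(a2)
  if (!any(complete)) {
    stop(sprintf("no typed data at locus %s", locus), call. = FALSE)
  }
  a1 <- a1[complete]
  a2 <- a2[complete]
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  counts <- table(key)
  counts <- counts[order(names(counts))]
  counts_int <- as.integer(counts)
  names(counts_int) <- names(counts)
  structure(
    list(locus = locus,
         counts = counts_int,
         alleles = sort(unique(c(a1, a2))),
         n_individuals = sum(complete),
         n_excluded = sum(!complete)),
    class = "genotype_count_table"
  )
}

# Build a genotype_count_table directly from named counts ("a/b" keys).
# Used by tests and the exact-test machinery.
#' Construct a genotype count table from named genotype counts
#'
#' @param counts Named integer vector; names are `allele1/allele2` pairs
#'   (order-insensitive; they are normalized to sorted order).
#' @param locus Locus label.
#' @return A `genotype_count_table`.
#' @export
genotype_table <- function(counts, locus = "locus") {
  stopifnot(length(counts) > 0L, !is.null(names(counts)), all(counts >= 0))
  parts <- strsplit(names(counts), "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("genotype names must be 'allele1/allele2' pairs", call. = FALSE)
  }
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  key <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  agg <- tapply(as.integer(counts), key, sum)
  counts_int <- as.integer(agg[order(names(agg))])
  names(counts_int) <- sort(names(agg))
  structure(
    list(locus = locus,
         counts = counts_int,
         alleles = sort(unique(c(a1, a2))),
         n_individuals = sum(counts_int),
         n_excluded = 0L),
    class = "genotype_count_table"
  )
}

# Gamete (allele) counts implied by a genotype table, in allele name order.
#' @keywords internal
#' @noRd
genotype_table_allele_counts <- function(gt) {
  parts <- strsplit(names(gt$counts), "/", fixed = TRUE)
  m <- integer(length(gt$alleles))
  names(m) <- gt$alleles
  for (i in seq_along(parts)) {
    m[parts[[i]][1]] <- m[parts[[i]][1]] + gt$counts[i]
    m[parts[[i]][2]] <- m[parts[[i]][2]] + gt$counts[i]
  }
  m
}

#' Observed homozygosity F
#'
#' The homozygosity statistic \eqn{F = \sum_i p_i^2} of an allele frequency
#' table; the statistic of the Ewens-Watterson test. Lies in `[1/k, 1]`.
#'
#' @param freq_table An `allele_freq_table`.
#' @return The proportion `F`.
#' @export
observed_homozygosity <- function(freq_table) {
  stopifnot(inherits(freq_table, "allele_freq_table"))
  sum(freq_table$freqs^2)
}
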