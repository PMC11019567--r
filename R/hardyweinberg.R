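# Tests of conformity to Hardy-Weinberg proportions.
#
# Two families: the chi-square goodness-of-fit test with pooling ("lumping")
# of rare genotype classes, and the conditional exact test, which evaluates
# the probability of the observed genotype table given the allele counts
#   P(table) = n! * prod_i m_i! * 2^H / ((2n)! * prod_{i<=j} n_ij!)
# (H = number of heterozygous individuals, m_i = gamete counts) either by
# full enumeration of all tables with the observed allele counts, or by
# Monte Carlo sampling from the same conditional distribution via random
# pairing of the 2n gamete labels.

LOGP_TOL <- 1e-12  # tie tolerance on log-probabilities

#' Chi-square test of Hardy-Weinberg proportions
#'
#' Goodness-of-fit test comparing observed genotype counts to Hardy-Weinberg
#' expectations \eqn{e_{ii} = n p_i^2}, \eqn{e_{ij} = 2 n p_i p_j}, with
#' allele frequencies estimated from the observed gamete counts. Genotype
#' classes with expected count below `lump_below` are pooled into a single
#' lumped class before computing the statistic. Degrees of freedom are
#' (number of classes after lumping) minus k, floored at 1.
#'
#' @param gt A `genotype_count_table`.
#' @param lump_below Pool classes with expected count below this (default 5).
#' @return An `hwe_chisq_result`: list with `chisq`, `df`, `pvalue`, a
#'   per-genotype data frame `table` (observed, expected, chi contribution,
#'   lumped flag), and `lumped` bookkeeping (class count, pooled
#'   observed/expected) or `NULL` when nothing was pooled.
#' @examples
#' gt <- genotype_table(c("A/A" = 30, "A/a" = 40, "a/a" = 30))
#' hwe_chisq(gt)$chisq  # 4.0
#' @export
hwe_chisq <- function(gt, lump_below = 5) {
  stopifnot(inherits(gt, "genotype_count_table"))
  m <- genotype_table_allele_counts(gt)
  k <- length(m)
  if (k < 2L) stop("monomorphic locus", call. = FALSE)
  n <- gt$n_individuals
  p <- m / (2 * n)
  alleles <- names(m)

  # all k(k+1)/2 genotype classes over observed alleles
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  name_of <- function(i, j) paste(pmin(alleles[i], alleles[j]),
                                  pmax(alleles[i], alleles[j]), sep = "/")
  cls <- name_of(idx[, 1], idx[, 2])
  expected <- ifelse(idx[, 1] == idx[, 2],
                     n * p[idx[, 1]]^2,
                     2 * n * p[idx[, 1]] * p[idx[, 2]])
  observed <- gt$counts[cls]
  observed[is.na(observed)] <- 0L

  lump <- expected < lump_below
  lumped <- NULL
  if (any(lump) && sum(lump) >= 1L) {
    obs_f <- c(observed[!lump], if (any(lump)) sum(observed[lump]))
    exp_f <- c(expected[!lump], if (any(lump)) sum(expected[lump]))
    lumped <- list(n_classes = sum(lump),
                   observed = sum(observed[lump]),
                   expected = sum(expected[lump]))
  } else {
    obs_f <- observed
    exp_f <- expected
  }
  # guard against a zero-expectation lumped class (cannot occur unless the
  # whole table is empty, which the constructor forbids)
  keep <- exp_f > 0
  obs_f <- obs_f[keep]
  exp_f <- exp_f[keep]
  chisq <- sum((obs_f - exp_f)^2 / exp_f)
  df <- max(1L, length(obs_f) - k)
  structure(
    list(chisq = chisq, df = df,
         pvalue = stats::pchisq(chisq, df, lower.tail = FALSE),
         table = data.frame(genotype = cls,
                            observed = as.integer(observed),
                            expected = unname(expected),
                            chi = unname((observed - expected)^2 / expected),
                            lumped = unname(lump),
                            row.names = NULL),
         lumped = lumped,
         lump_below = lump_below,
         n_individuals = n, k = k),
    class = "hwe_chisq_result"
  )
}

# log P(table | allele counts) for an internal integer representation:
# tab is a k x k upper-triangular matrix of genotype counts (n_ij, i <= j).
#' @keywords internal
#' @noRd
log_table_probability <- function(tab, m = NULL) {
  k <- nrow(tab)
  n <- sum(tab)
  if (is.null(m)) {
    m <- colSums(tab) + rowSums(tab)   # diagonal counted twice: see below
    # rowSums+colSums counts n_ii twice already (once in each), which is the
    # gamete count contribution we want.
  }
  het <- sum(tab[upper.tri(tab)])
  lgamma(n + 1) + sum(lgamma(m + 1)) + het * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(tab[upper.tri(tab, diag = TRUE)] + 1))
}

#' Conditional probability of a genotype table given its allele counts
#'
#' Evaluates \eqn{P = n!\,\prod_i m_i!\,2^H / ((2n)!\,\prod_{i\le j} n_{ij}!)},
#' the probability of the observed genotype table under Hardy-Weinberg
#' proportions conditional on the observed gamete counts. Over all tables
#' sharing the same allele counts these probabilities sum to 1.
#'
#' @param gt A `genotype_count_table`.
#' @return The probability, in (0, 1].
#' @examples
#' genotype_table_probability(genotype_table(c("A/a" = 2)))  # 2/3
#' @export
genotype_table_probability <- function(gt) {
  stopifnot(inherits(gt, "genotype_count_table"))
  tab <- gt_as_matrix(gt)
  exp(log_table_probability(tab))
}

#' @keywords internal
#' @noRd
gt_as_matrix <- function(gt) {
  alleles <- gt$alleles
  k <- length(alleles)
  tab <- matrix(0L, k, k, dimnames = list(alleles, alleles))
  parts <- strsplit(names(gt$counts), "/", fixed = TRUE)
  for (i in seq_along(parts)) {
    a <- match(parts[[i]][1], alleles)
    b <- match(parts[[i]][2], alleles)
    tab[min(a, b), max(a, b)] <- tab[min(a, b), max(a, b)] + gt$counts[i]
  }
  tab
}

# Enumerate all genotype tables (upper-triangular k x k integer matrices)
# with the given gamete counts m. Calls `emit(tab)` for each; stops with a
# classed condition once more than max_tables tables have been produced.
#' @keywords internal
#' @noRd
enumerate_genotype_tables <- function(m, emit, max_tables = Inf) {
  k <- length(m)
  tab <- matrix(0L, k, k)
  count <- 0L

  fill_row <- function(i, remaining) {
    if (i == k) {
      if (remaining[k] %% 2L == 0L) {
        tab[k, k] <<- remaining[k] %/% 2L
        count <<- count + 1L
        if (count > max_tables) {
          stop(structure(
            class = c("hlapop_enumeration_overflow", "error", "condition"),
            list(message = "table enumeration exceeds max_tables; use Monte Carlo",
                 call = NULL)))
        }
        emit(tab)
      }
      return(invisible())
    }
    for (nii in 0:(remaining[i] %/% 2L)) {
      tab[i, i] <<- nii
      distribute(i, i + 1L, remaining[i] - 2L * nii, remaining)
    }
    invisible()
  }

  distribute <- function(i, j, left, remaining) {
    if (j > k) {
      if (left == 0L) fill_row(i + 1L, remaining)
      return(invisible())
    }
    if (j == k) {
      if (left <= remaining[k]) {
        tab[i, k] <<- left
        rem2 <- remaining
        rem2[k] <- rem2[k] - left
        fill_row(i + 1L, rem2)
        tab[i, k] <<- 0L
      }
      return(invisible())
    }
    for (nij in 0:min(left, remaining[j])) {
      tab[i, j] <<- nij
      rem2 <- remaining
      rem2[j] <- rem2[j] - nij
      distribute(i, j + 1L, left - nij, rem2)
      tab[i, j] <<- 0L
    }
    invisible()
  }

  fill_row(1L, as.integer(m))
  invisible(count)
}

#' Exact Hardy-Weinberg test by full enumeration
#'
#' Enumerates every genotype table compatible with the observed allele
#' counts and sums the conditional probabilities of tables as extreme as the
#' observed one: the overall p-value sums `P(table) <= P(observed)`, and the
#' heterozygote tail tests sum over tables whose heterozygote count is at
#' least (excess) or at most (deficit) the observed count.
#'
#' @param gt A `genotype_count_table`.
#' @param max_tables Abort (with a classed error asking for Monte Carlo)
#'   when the enumeration exceeds this many tables.
#' @return An `hwe_exact_result` with `p_overall`, `p_het_excess`,
#'   `p_het_deficit`, `method = "enumeration"`, `n_tables_enumerated`,
#'   `prob_sum` (enumeration total, equals 1 up to rounding) and the
#'   observed table probability `p_observed`.
#' @export
hwe_exact_enumeration <- function(gt, max_tables = 5e4) {
  stopifnot(inherits(gt, "genotype_count_table"))
  m <- genotype_table_allele_counts(gt)
  tab_obs <- gt_as_matrix(gt)
  lp_obs <- log_table_probability(tab_obs)
  het_obs <- sum(tab_obs[upper.tri(tab_obs)])

  acc <- new.env(parent = emptyenv())
  acc$total <- 0
  acc$p_le <- 0
  acc$het_ge <- 0
  acc$het_le <- 0
  acc$n <- 0L
  emit <- function(tab) {
    lp <- log_table_probability(tab)
    pr <- exp(lp)
    het <- sum(tab[upper.tri(tab)])
    acc$total <- acc$total + pr
    if (lp <= lp_obs + LOGP_TOL) acc$p_le <- acc$p_le + pr
    if (het >= het_obs) acc$het_ge <- acc$het_ge + pr
    if (het <= het_obs) acc$het_le <- acc$het_le + pr
    acc$n <- acc$n + 1L
  }
  enumerate_genotype_tables(m, emit, max_tables = max_tables)

  structure(
    list(p_overall = min(1, acc$p_le),
         p_het_excess = min(1, acc$het_ge),
         p_het_deficit = min(1, acc$het_le),
         method = "enumeration",
         n_tables_enumerated = acc$n,
         prob_sum = acc$total,
         p_observed = exp(lp_obs),
         het_observed = het_obs,
         seed = NA_integer_),
    class = "hwe_exact_result"
  )
}

#' Exact Hardy-Weinberg test by Monte Carlo
#'
#' Samples genotype tables from the conditional distribution given the
#' observed allele counts by randomly shuffling the 2n gamete labels into n
#' pairs, and estimates the same tail probabilities as
#' [hwe_exact_enumeration()] with the add-one convention
#' \eqn{\hat p = (1 + x)/(1 + N)} so that no estimate is exactly zero.
#'
#' @param gt A `genotype_count_table`.
#' @param n_samples Number of Monte Carlo tables (default 10000).
#' @param seed Integer seed; a fixed seed reproduces the result exactly.
#' @return An `hwe_exact_result` with `method = "montecarlo"` and `n_steps`.
#' @export
hwe_exact_montecarlo <- function(gt, n_samples = 10000, seed = NULL) {
  stopifnot(inherits(gt, "genotype_count_table"), n_samples >= 1)
  m <- genotype_table_allele_counts(gt)
  k <- length(m)
  n <- gt$n_individuals
  tab_obs <- gt_as_matrix(gt)
  lp_obs <- log_table_probability(tab_obs)
  het_obs <- sum(tab_obs[upper.tri(tab_obs)])
  gametes <- rep.int(seq_len(k), times = m)

  sample_once <- function() {
    perm <- sample(gametes)
    a <- perm[seq(1L, 2L * n, by = 2L)]
    b <- perm[seq(2L, 2L * n, by = 2L)]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    tab <- matrix(0L, k, k)
    # accumulate pair counts into the upper triangle
    flat <- (hi - 1L) * k + lo   # column-major index of [lo, hi]
    tb <- tabulate(flat, nbins = k * k)
    tab[] <- tb
    tab
  }

  x_le <- 0L; x_ge <- 0L; x_de <- 0L
  with_seed(seed, {
    for (s in seq_len(n_samples)) {
      tab <- sample_once()
      lp <- log_table_probability(tab, m)
      if (lp <= lp_obs + LOGP_TOL) x_le <- x_le + 1L
      het <- sum(tab[upper.tri(tab)])
      if (het >= het_obs) x_ge <- x_ge + 1L
      if (het <= het_obs) x_de <- x_de + 1L
    }
  })
  structure(
    list(p_overall = (1 + x_le) / (1 + n_samples),
         p_het_excess = (1 + x_ge) / (1 + n_samples),
         p_het_deficit = (1 + x_de) / (1 + n_samples),
         method = "montecarlo",
         n_steps = as.integer(n_samples),
         p_observed = exp(lp_obs),
         het_observed = het_obs,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "hwe_exact_result"
  )
}

#' Exact Hardy-Weinberg test, choosing enumeration when feasible
#'
#' Runs [hwe_exact_enumeration()] and falls back to
#' [hwe_exact_montecarlo()] when the enumeration would exceed `max_tables`.
#'
#' @inheritParams hwe_exact_montecarlo
#' @inheritParams hwe_exact_enumeration
#' @return An `hwe_exact_result`.
#' @export
hwe_exact_test <- function(gt, max_tables = 5e4, n_samples = 10000, seed = NULL) {
  tryCatch(
    hwe_exact_enumeration(gt, max_tables = max_tables),
    hlapop_enumeration_overflow = function(e) {
      hwe_exact_montecarlo(gt, n_samples = n_samples, seed = seed)
    }
  )
}
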