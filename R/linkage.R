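# Pairwise linkage disequilibrium from haplotype frequencies: the
# haplotype-level coefficients D_ij and their normalized D'_ij, the
# frequency-weighted overall D', the multiallelic correlation Wn, and the
# asymmetric ALD measures W12/W21 (overall LD conditional on the second and
# first locus, respectively). For two biallelic loci W12 and W21 both
# reduce to the usual |r| of SNP analyses.

ALD_CLAMP <- 1e-12  # tiny negative radicands are rounded up to zero

check_marginals <- function(h, p, q, tol = 1e-9) {
  if (max(abs(rowSums(h) - p)) > tol || max(abs(colSums(h) - q)) > tol) {
    stop("haplotype frequencies inconsistent with allele-frequency marginals",
         call. = FALSE)
  }
}

#' Haplotype-level LD coefficients
#'
#' Computes, for every haplotype (i, j), the coefficient
#' \eqn{D_{ij} = h_{ij} - p_i q_j} and its range-normalized form
#' \eqn{D'_{ij} = D_{ij} / D_{max}} where \eqn{D_{max}} is
#' \eqn{\min(p_i q_j, (1-p_i)(1-q_j))} for negative \eqn{D_{ij}} and
#' \eqn{\min(p_i (1-q_j), (1-p_i) q_j)} for positive \eqn{D_{ij}};
#' \eqn{D'_{ij} = 0} when \eqn{D_{ij} = 0}.
#'
#' @param h Numeric I x J matrix of haplotype frequencies (rows = locus-1
#'   alleles, columns = locus-2 alleles), summing to 1.
#' @param p,q Allele frequencies at locus 1 / locus 2; defaults are the row
#'   and column sums of `h`. Supplied values must agree with the margins of
#'   `h` to 1e-9.
#' @return A list with matrices `d` and `dprime` and the vectors `p`, `q`.
#' @export
ld_coefficients <- function(h, p = NULL, q = NULL) {
  stopifnot(is.matrix(h), all(h >= 0))
  if (abs(sum(h) - 1) > 1e-9) stop("haplotype frequencies must sum to 1", call. = FALSE)
  if (is.null(p)) p <- rowSums(h) else check_marginals(h, p, colSums(h))
  if (is.null(q)) q <- colSums(h) else check_marginals(h, rowSums(h), q)
  check_marginals(h, p, q)
  d <- h - outer(p, q)
  dmax_neg <- pmin(outer(p, q), outer(1 - p, 1 - q))
  dmax_pos <- pmin(outer(p, 1 - q), outer(1 - p, q))
  dmax <- ifelse(d < 0, dmax_neg, dmax_pos)
  dprime <- ifelse(d == 0, 0, d / dmax)
  list(d = d, dprime = dprime, p = p, q = q)
}

#' Overall D' summary of pairwise LD
#'
#' The allele-frequency-weighted mean of the absolute normalized
#' haplotype-level coefficients: \eqn{D' = \sum_i \sum_j p_i q_j |D'_{ij}|}.
#'
#' @param dprime Matrix of haplotype-level normalized coefficients (from
#'   [ld_coefficients()]).
#' @param p,q Allele frequency vectors.
#' @return A proportion in `[0, 1]`.
#' @export
dprime_overall <- function(dprime, p, q) {
  sum(outer(p, q) * abs(dprime))
}

#' Overall Wn (Cramer-type) summary of pairwise LD
#'
#' The multiallelic extension of the SNP correlation \eqn{r}:
#' \eqn{W_n = \sqrt{\sum_{ij} D_{ij}^2/(p_i q_j) / \min(I-1, J-1)}}.
#' For two biallelic loci this equals |r|.
#'
#' @param d Matrix of haplotype-level coefficients `D_ij`.
#' @param p,q Allele frequency vectors.
#' @return A proportion in `[0, 1]`, or `NA` when either locus is
#'   monomorphic (the measure is undefined).
#' @export
wn_overall <- function(d, p, q) {
  I <- length(p); J <- length(q)
  if (I < 2L || J < 2L) return(NA_real_)
  w2 <- sum(d^2 / outer(p, q)) / min(I - 1L, J - 1L)
  min(1, sqrt(max(0, w2)))
}

#' Asymmetric LD measures W12 and W21
#'
#' ALD compares conditional to unconditional homozygosity. With
#' \eqn{F_1 = \sum_i p_i^2} and the conditional
#' \eqn{F_{1|2} = \sum_j \sum_i h_{ij}^2 / q_j},
#' \eqn{W_{12} = \sqrt{(F_{1|2} - F_1)/(1 - F_1)}} measures overall LD for
#' locus 1 conditioned on locus 2 (reported as `ALD_1_2`), and symmetrically
#' \eqn{W_{21} = \sqrt{(F_{2|1} - F_2)/(1 - F_2)}} conditions on locus 1.
#' The two differ when the loci carry different numbers of alleles. A
#' measure is undefined (`NA`) when its focal locus is monomorphic.
#'
#' @inheritParams ld_coefficients
#' @return Named numeric vector `c(w12, w21)`.
#' @examples
#' h <- matrix(c(0.5, 0, 0, 0.5), 2)  # complete LD
#' ald_pair(h)  # both 1
#' @export
ald_pair <- function(h, p = NULL, q = NULL) {
  stopifnot(is.matrix(h), all(h >= 0))
  if (abs(sum(h) - 1) > 1e-9) stop("haplotype frequencies must sum to 1", call. = FALSE)
  if (is.null(p)) p <- rowSums(h) else check_marginals(h, p, colSums(h))
  if (is.null(q)) q <- colSums(h) else check_marginals(h, rowSums(h), q)
  check_marginals(h, p, q)

  ald_one <- function(hm, pfocal, qcond) {
    Ff <- sum(pfocal^2)
    if (1 - Ff <= ALD_CLAMP) return(NA_real_)
    pos <- qcond > 0
    Fcond <- sum(sweep(hm[, pos, drop = FALSE]^2, 2L, qcond[pos], "/"))
    rad <- (Fcond - Ff) / (1 - Ff)
    if (rad < 0) {
      if (rad < -ALD_CLAMP) {
        stop("negative ALD radicand beyond tolerance: inconsistent input",
             call. = FALSE)
      }
      rad <- 0
    }
    min(1, sqrt(rad))
  }
  c(w12 = ald_one(h, p, q),          # locus 1 conditioned on locus 2
    w21 = ald_one(t(h), q, p))       # locus 2 conditioned on locus 1
}

#' Pairwise LD between two loci of a dataset
#'
#' Estimates two-locus haplotype frequencies by EM ([estimate_haplotypes()])
#' and computes the haplotype-level coefficients plus the summary measures
#' D', Wn and the asymmetric ALD pair. Sampling error of the EM estimate is
#' not propagated; significance comes from the optional permutation test
#' (`n_permutations > 0`).
#'
#' @param dataset A `pop_dataset`.
#' @param locus1,locus2 Locus names.
#' @param n_permutations Number of permutations for the significance test;
#'   0 (default) skips it and permutation fields are absent from reports.
#' @param seed Integer seed (drives the permutation test).
#' @param ... Passed to [estimate_haplotypes()].
#' @return An `ld_pair_result`: list with `locus1`, `locus2`, `I`, `J`,
#'   `h` (haplotype frequency matrix), `d`, `dprime` (matrices), `p`, `q`,
#'   `dprime_overall`, `wn`, `ald_1_2`, `ald_2_1`, `n_individuals`, the
#'   underlying `estimate`, and `permutation` (`NULL` unless run).
#' @export
ld_pair <- function(dataset, locus1, locus2, n_permutations = 0L, seed = NULL,
                    ...) {
  est <- estimate_haplotypes(dataset, c(locus1, locus2), ...)
  h <- haplotype_freq_matrix(est)
  co <- ld_coefficients(h)
  ald <- ald_pair(h, co$p, co$q)
  perm <- NULL
  if (n_permutations > 0L) {
    perm <- ld_permutation_test(dataset, locus1, locus2,
                                n_permutations = n_permutations, seed = seed,
                                ...)
  }
  structure(
    list(locus1 = locus1, locus2 = locus2,
         I = nrow(h), J = ncol(h),
         h = h, d = co$d, dprime = co$dprime, p = co$p, q = co$q,
         dprime_overall = dprime_overall(co$dprime, co$p, co$q),
         wn = wn_overall(co$d, co$p, co$q),
         ald_1_2 = unname(ald["w12"]), ald_2_1 = unname(ald["w21"]),
         n_individuals = est$n_individuals,
         estimate = est,
         permutation = perm),
    class = "ld_pair_result"
  )
}

# Two-locus haplotype frequency matrix from a haplotype estimate.
#' @keywords internal
#' @noRd
haplotype_freq_matrix <- function(est) {
  stopifnot(length(est$loci) == 2L)
  parts <- strsplit(names(est$freqs), "~", fixed = TRUE)
  a1 <- vapply(parts, `[`, "", 1L)
  a2 <- vapply(parts, `[`, "", 2L)
  r <- sort(unique(a1)); s <- sort(unique(a2))
  h <- matrix(0, length(r), length(s), dimnames = list(r, s))
  h[cbind(match(a1, r), match(a2, s))] <- unname(est$freqs)
  h / sum(h)
}

#' Permutation test of pairwise LD significance
#'
#' The observed statistic is Wn from the EM haplotype estimate. The null is
#' generated by randomly permuting the locus-2 single-locus genotypes
#' across individuals -- preserving both single-locus genotype
#' distributions while destroying between-locus association -- and
#' re-estimating haplotypes for each permutation. The p-value uses the
#' add-one convention \eqn{(1 + \#\{W_n^{perm} \ge W_n^{obs}\})/(1 + N)}.
#'
#' @inheritParams ld_pair
#' @param n_permutations Number of permutations (>= 1).
#' @param max_redraws Cap on re-drawn permutations after estimation errors.
#' @param ... Passed to [estimate_haplotypes()].
#' @return A list with `n_permutations`, `p_value`, `statistic` (`"wn"`),
#'   `stat_obs`, `seed` and `n_redraws`.
#' @export
ld_permutation_test <- function(dataset, locus1, locus2, n_permutations,
                                seed = NULL, max_redraws = 100L, ...) {
  stopifnot(n_permutations >= 1L)
  pair_wn <- function(ds) {
    est <- estimate_haplotypes(ds, c(locus1, locus2), ...)
    h <- haplotype_freq_matrix(est)
    wn_overall(h - outer(rowSums(h), colSums(h)), rowSums(h), colSums(h))
  }
  stat_obs <- pair_wn(dataset)
  if (is.na(stat_obs)) {
    stop("Wn undefined (monomorphic locus); permutation test not applicable",
         call. = FALSE)
  }
  j2 <- match(locus2, dataset$loci)
  n <- n_individuals(dataset)
  x_ge <- 0L
  n_redraws <- 0L
  with_seed(seed, {
    done <- 0L
    while (done < n_permutations) {
      perm <- sample.int(n)
      ds <- dataset
      ds$allele1[, j2] <- dataset$allele1[perm, j2]
      ds$allele2[, j2] <- dataset$allele2[perm, j2]
      stat <- tryCatch(pair_wn(ds), error = function(e) NA_real_)
      if (is.na(stat)) {
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws) {
          stop("too many failed permutations", call. = FALSE)
        }
        next
      }
      if (stat >= stat_obs - 1e-12) x_ge <- x_ge + 1L
      done <- done + 1L
    }
  })
  list(n_permutations = as.integer(n_permutations),
       p_value = (1 + x_ge) / (1 + n_permutations),
       statistic = "wn",
       stat_obs = stat_obs,
       seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
       n_redraws = n_redraws)
}
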