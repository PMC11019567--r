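# EM estimation of multi-locus haplotype frequencies from unphased
# genotype data.
#
# Each individual complete at the requested loci contributes the set of
# phase-consistent haplotype pairs (2^(h-1) of them for h >= 1 heterozygous
# loci). The E-step weights pair (h1, h2) by f(h1) f(h2) (times 2 when
# h1 != h2), normalized within the individual; the M-step sets each
# haplotype frequency to its expected gamete count over 2n. The observed
# data log-likelihood is non-decreasing across iterations.

DEFAULT_LOCUS_CAP <- 8L
REPORT_FREQ_FLOOR <- 1e-8   # haplotypes below this are dropped from reports

#' Enumerate phase-consistent haplotype resolutions
#'
#' For each individual complete at all requested loci, lists every ordered
#' pair of haplotypes consistent with the unphased genotypes: one
#' resolution when at most one locus is heterozygous, otherwise
#' \eqn{2^{h-1}} for h heterozygous loci. Individuals untyped at any
#' requested locus are excluded listwise and counted.
#'
#' @param dataset A `pop_dataset`.
#' @param loci Character vector of locus names (2 or more typical; 1 works).
#' @param max_loci Cap on the number of loci (default 8).
#' @param max_resolutions Cap on resolutions per individual.
#' @return A `resolution_set`: list with parallel vectors `individual`,
#'   `hap1`, `hap2` (haplotype names, `~`-joined), plus `loci`,
#'   `n_individuals` (included) and `n_excluded`.
#' @export
enumerate_resolutions <- function(dataset, loci, max_loci = DEFAULT_LOCUS_CAP,
                                  max_resolutions = 4096L) {
  stopifnot(inherits(dataset, "pop_dataset"))
  missing_loci <- setdiff(loci, dataset$loci)
  if (length(missing_loci) > 0L) {
    stop("loci not in dataset: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  }
  if (length(loci) > max_loci) {
    stop(sprintf("%d loci requested; cap is %d", length(loci), max_loci),
         call. = FALSE)
  }
  jj <- match(loci, dataset$loci)
  a1 <- dataset$allele1[, jj, drop = FALSE]
  a2 <- dataset$allele2[, jj, drop = FALSE]
  complete <- rowSums(is.na(a1) | is.na(a2)) == 0L
  if (!any(complete)) {
    stop("no individuals complete at the requested loci", call. = FALSE)
  }
  a1 <- a1[complete, , drop = FALSE]
  a2 <- a2[complete, , drop = FALSE]
  n <- nrow(a1)
  L <- length(loci)

  ind <- integer(0); hap1 <- character(0); hap2 <- character(0)
  ind_l <- vector("list", n); h1_l <- vector("list", n); h2_l <- vector("list", n)
  for (r in seq_len(n)) {
    het <- which(a1[r, ] != a2[r, ])
    h <- length(het)
    n_res <- if (h <= 1L) 1L else 2L^(h - 1L)
    if (n_res > max_resolutions) {
      stop(sprintf("individual %d has %d phase resolutions; cap is %d",
                   which(complete)[r], n_res, max_resolutions), call. = FALSE)
    }
    g1 <- matrix(rep(a1[r, ], n_res), nrow = n_res, byrow = TRUE)
    g2 <- matrix(rep(a2[r, ], n_res), nrow = n_res, byrow = TRUE)
    if (h >= 2L) {
      # first heterozygous locus fixed; remaining h-1 flip by bit pattern
      for (b in seq_len(h - 1L)) {
        flip <- bitwAnd(seq_len(n_res) - 1L, bitwShiftL(1L, b - 1L)) > 0L
        loc <- het[b + 1L]
        tmp <- g1[flip, loc]
        g1[flip, loc] <- g2[flip, loc]
        g2[flip, loc] <- tmp
      }
    }
    h1_l[[r]] <- apply(g1, 1L, paste, collapse = "~")
    h2_l[[r]] <- apply(g2, 1L, paste, collapse = "~")
    ind_l[[r]] <- rep.int(r, n_res)
  }
  structure(
    list(individual = unlist(ind_l), hap1 = unlist(h1_l), hap2 = unlist(h2_l),
         loci = loci, n_individuals = n, n_excluded = sum(!complete)),
    class = "resolution_set"
  )
}

#' EM estimate of haplotype frequencies
#'
#' Runs the expectation-maximization algorithm on a resolution set.
#' Iteration stops when the largest absolute frequency change drops below
#' `tol` or after `max_iter` iterations. Restart 0 initializes uniformly
#' over the observed haplotypes; additional restarts draw random simplex
#' initializations under `seed`, and the run with the best final
#' log-likelihood is returned.
#'
#' @param resolutions A `resolution_set` from [enumerate_resolutions()].
#' @param tol Convergence tolerance on max |change in f| (default 1e-7).
#' @param max_iter Maximum EM iterations per restart (default 1000).
#' @param n_restarts Total number of EM runs (default 1 = uniform start only).
#' @param seed Integer seed for the random restarts.
#' @return A `haplotype_estimate`: list with `loci`, `freqs` (named, sums to
#'   1), `counts` (`freqs` times 2n), `loglik`, `loglik_history`,
#'   `n_iterations`, `converged`, `n_restarts`, `seed`, `n_individuals`,
#'   `n_excluded`.
#' @export
em_estimate <- function(resolutions, tol = 1e-7, max_iter = 1000L,
                        n_restarts = 1L, seed = NULL) {
  stopifnot(inherits(resolutions, "resolution_set"))
  haps <- sort(unique(c(resolutions$hap1, resolutions$hap2)))
  H <- length(haps)
  i1 <- match(resolutions$hap1, haps)
  i2 <- match(resolutions$hap2, haps)
  ind <- resolutions$individual
  n <- resolutions$n_individuals
  het <- i1 != i2
  mult <- ifelse(het, 2, 1)

  run_em <- function(f0) {
    f <- f0
    history <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      w <- f[i1] * f[i2] * mult
      tot <- rowsum(w, ind)[, 1L]
      history <- c(history, sum(log(tot)))
      wn <- w / tot[ind]
      cnt <- rowsum(c(wn, wn), c(i1, i2))
      f_new <- numeric(H)
      f_new[as.integer(rownames(cnt))] <- cnt[, 1L]
      f_new <- f_new / (2 * n)
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    # final log-likelihood at the returned frequencies
    w <- f[i1] * f[i2] * mult
    tot <- rowsum(w, ind)[, 1L]
    history <- c(history, sum(log(tot)))
    list(f = f, loglik = history[length(history)], history = history,
         iter = iter, converged = converged)
  }

  starts <- list(rep(1 / H, H))
  if (n_restarts > 1L) {
    extra <- with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(i) {
        x <- stats::rexp(H)
        x / sum(x)
      })
    })
    starts <- c(starts, extra)
  }
  runs <- lapply(starts, run_em)
  best <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]

  freqs <- best$f
  names(freqs) <- haps
  structure(
    list(loci = resolutions$loci,
         freqs = freqs,
         counts = freqs * 2 * n,
         loglik = best$loglik,
         loglik_history = best$history,
         n_iterations = best$iter,
         converged = best$converged,
         n_restarts = as.integer(n_restarts),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         n_individuals = n,
         n_excluded = resolutions$n_excluded),
    class = "haplotype_estimate"
  )
}

#' Estimate haplotype frequencies for a locus set
#'
#' Convenience wrapper: [enumerate_resolutions()] then [em_estimate()].
#'
#' @inheritParams enumerate_resolutions
#' @inheritParams em_estimate
#' @return A `haplotype_estimate`.
#' @export
estimate_haplotypes <- function(dataset, loci, tol = 1e-7, max_iter = 1000L,
                                n_restarts = 1L, seed = NULL,
                                max_loci = DEFAULT_LOCUS_CAP) {
  res <- enumerate_resolutions(dataset, loci, max_loci = max_loci)
  em_estimate(res, tol = tol, max_iter = max_iter,
              n_restarts = n_restarts, seed = seed)
}

# Haplotypes above the reporting floor, as a data frame in decreasing
# frequency order. Used by the report writers.
#' @keywords internal
#' @noRd
haplotype_report_table <- function(est, floor = REPORT_FREQ_FLOOR) {
  keep <- est$freqs >= floor
  f <- est$freqs[keep]
  ord <- order(-f, names(f))
  data.frame(haplotype = names(f)[ord],
             frequency = unname(f[ord]),
             count = unname(f[ord]) * 2 * est$n_individuals,
             row.names = NULL)
}
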