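# Ewens-Watterson homozygosity test of neutrality.
#
# Under the neutral null, conditional on the number of gametes n and the
# number of distinct alleles k, the allele-count configuration follows the
# Ewens sampling formula with the mutation parameter integrated out:
#   P(config) = n! / (prod_j j^{a_j} a_j!) / |s(n, k)|
# where a_j is the number of alleles observed j times and |s(n,k)| is the
# unsigned Stirling number of the first kind. The test compares observed
# homozygosity F = sum p_i^2 to this conditional null, either by complete
# enumeration of the partitions of n into k parts or by Monte Carlo
# sampling (Hoppe-urn runs conditioned on realizing k alleles).

F_TOL <- 1e-12  # tie tolerance when comparing homozygosity values

# log |s(n, k)| via the triangular recurrence, computed in log space.
#' @keywords internal
#' @noRd
log_stirling1_unsigned <- function(n, k) {
  stopifnot(n >= 1, k >= 1, k <= n)
  # ls[j+1] = log |s(m, j)| for the current m
  ls <- rep(-Inf, n + 1)
  ls[2] <- 0                  # m = 1: s(1,1) = 1
  if (n > 1) {
    for (m in 2:n) {
      new <- rep(-Inf, n + 1)
      for (j in 1:m) {
        a <- if (j >= 2) ls[j] else -Inf          # |s(m-1, j-1)|
        b <- ls[j + 1] + log(m - 1)               # (m-1) |s(m-1, j)|
        new[j + 1] <- if (is.infinite(a)) b else if (is.infinite(b)) a else
          max(a, b) + log1p(exp(-abs(a - b)))
      }
      ls <- new
    }
  }
  ls[k + 1]
}

#' Probability of an allele-count configuration under the conditional Ewens
#' sampling formula
#'
#' @param config Integer vector of allele counts (a partition of `n` into
#'   `k` positive parts; order is irrelevant).
#' @param n Total gamete count; defaults to `sum(config)`.
#' @param k Number of alleles; defaults to `length(config)`.
#' @return The probability of the configuration, in (0, 1]. Probabilities
#'   sum to 1 over all partitions of `n` into `k` parts.
#' @examples
#' esf_config_probability(c(3, 1))  # 8/11
#' esf_config_probability(c(2, 2))  # 3/11
#' @export
esf_config_probability <- function(config, n = sum(config), k = length(config)) {
  config <- as.integer(config)
  if (any(config < 1L)) stop("configuration parts must be positive", call. = FALSE)
  if (sum(config) != n || length(config) != k) {
    stop("inconsistent configuration: parts must sum to n with k parts", call. = FALSE)
  }
  a <- tabulate(config, nbins = n)
  j <- which(a > 0L)
  logw <- lgamma(n + 1) - sum(a[j] * log(j) + lgamma(a[j] + 1))
  exp(logw - log_stirling1_unsigned(n, k))
}

# Enumerate partitions of n into exactly k parts (non-increasing order),
# calling emit(parts) for each; errors past max_partitions.
#' @keywords internal
#' @noRd
enumerate_partitions <- function(n, k, emit, max_partitions = Inf) {
  parts <- integer(k)
  count <- 0L
  rec <- function(pos, left, maxpart) {
    if (pos == k) {
      if (left >= 1L && left <= maxpart) {
        parts[k] <<- left
        count <<- count + 1L
        if (count > max_partitions) {
          stop(structure(
            class = c("hlapop_enumeration_overflow", "error", "condition"),
            list(message = "partition enumeration exceeds max_partitions; use Monte Carlo",
                 call = NULL)))
        }
        emit(parts)
      }
      return(invisible())
    }
    remaining_slots <- k - pos
    # part at pos must be >= ceil(left / (remaining_slots + 1)) so the rest fits
    lo <- ceiling(left / (remaining_slots + 1L))
    hi <- min(maxpart, left - remaining_slots)
    if (hi < lo) return(invisible())
    for (v in hi:lo) {
      parts[pos] <<- v
      rec(pos + 1L, left - v, v)
    }
    invisible()
  }
  rec(1L, as.integer(n), as.integer(n))
  invisible(count)
}

ew_result <- function(F_obs, E_F, sd_F, p_value, p_upper, method,
                      n, k, extra = list()) {
  structure(
    c(list(F_obs = F_obs, E_F = E_F, sd_F = sd_F,
           F_nd = if (sd_F > 0) (F_obs - E_F) / sd_F else NA_real_,
           p_value = p_value, p_upper = p_upper,
           method = method, n_gametes = n, k = k),
      extra),
    class = "ew_result"
  )
}

#' Ewens-Watterson exact test of neutrality
#'
#' Enumerates every allele-count configuration (partition of the gamete
#' count n into k parts), weights each by its conditional Ewens sampling
#' formula probability, and reports the lower-tail p-value
#' \eqn{P(F \le F_{obs})} (small F indicates balancing selection) together
#' with the exact null mean and standard deviation of F and the normalized
#' deviate `F_nd`.
#'
#' @param freq_table An `allele_freq_table`.
#' @param max_partitions Abort (with a classed error asking for Monte
#'   Carlo) past this many partitions.
#' @return An `ew_result` with `method = "enumeration"`, including the
#'   upper-tail probability `p_upper` and `n_partitions`.
#' @export
ew_exact_test <- function(freq_table, max_partitions = 5e5) {
  stopifnot(inherits(freq_table, "allele_freq_table"))
  n <- freq_table$n_gametes
  k <- freq_table$k
  F_obs <- observed_homozygosity(freq_table)

  log_norm <- log_stirling1_unsigned(n, k)
  acc <- new.env(parent = emptyenv())
  acc$total <- 0; acc$p_le <- 0; acc$p_ge <- 0
  acc$m1 <- 0; acc$m2 <- 0; acc$count <- 0L
  emit <- function(parts) {
    a <- tabulate(parts, nbins = n)
    j <- which(a > 0L)
    pr <- exp(lgamma(n + 1) - sum(a[j] * log(j) + lgamma(a[j] + 1)) - log_norm)
    f <- sum((parts / n)^2)
    acc$total <- acc$total + pr
    if (f <= F_obs + F_TOL) acc$p_le <- acc$p_le + pr
    if (f >= F_obs - F_TOL) acc$p_ge <- acc$p_ge + pr
    acc$m1 <- acc$m1 + pr * f
    acc$m2 <- acc$m2 + pr * f^2
    acc$count <- acc$count + 1L
  }
  enumerate_partitions(n, k, emit, max_partitions = max_partitions)

  E_F <- acc$m1
  var_F <- max(0, acc$m2 - E_F^2)
  ew_result(F_obs, E_F, sqrt(var_F),
            p_value = min(1, acc$p_le), p_upper = min(1, acc$p_ge),
            method = "enumeration", n = n, k = k,
            extra = list(n_partitions = acc$count, prob_sum = acc$total,
                         seed = NA_integer_))
}

# Solve E[K(theta, n)] = sum_{i=0}^{n-1} theta/(theta+i) = k for theta.
#' @keywords internal
#' @noRd
solve_theta_for_k <- function(n, k) {
  stopifnot(k > 1, k < n)
  f <- function(th) sum(th / (th + 0:(n - 1))) - k
  lo <- 1e-8; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# One Hoppe-urn (Chinese restaurant) run of n gametes at parameter theta;
# returns the allele-count configuration.
#' @keywords internal
#' @noRd
hoppe_urn_run <- function(n, theta) {
  counts <- integer(0)
  for (m in seq_len(n)) {
    if (stats::runif(1) < theta / (theta + m - 1)) {
      counts <- c(counts, 1L)
    } else {
      i <- sample.int(length(counts), 1L, prob = counts)
      counts[i] <- counts[i] + 1L
    }
  }
  counts
}

#' Ewens-Watterson test by Monte Carlo sampling
#'
#' Samples allele-count configurations from the Ewens sampling formula
#' conditional on the observed allele number k, by running a Hoppe urn with
#' the mutation parameter solved from \eqn{E[K(\theta, n)] = k} and
#' rejecting runs whose realized allele number differs from k. The p-value
#' uses the add-one convention \eqn{(1 + x)/(1 + N)}; `E_F` and `sd_F` are
#' sample moments of the accepted configurations.
#'
#' @param freq_table An `allele_freq_table`.
#' @param n_samples Number of accepted configurations to draw.
#' @param seed Integer seed for reproducibility.
#' @param max_attempts Cap on total urn runs before giving up (the error
#'   reports the acceptance rate).
#' @return An `ew_result` with `method = "montecarlo"`.
#' @export
ew_montecarlo_test <- function(freq_table, n_samples = 2000, seed = NULL,
                               max_attempts = 1e6) {
  stopifnot(inherits(freq_table, "allele_freq_table"), n_samples >= 1)
  n <- freq_table$n_gametes
  k <- freq_table$k
  F_obs <- observed_homozygosity(freq_table)

  # degenerate conditionals have a single configuration
  if (k == 1L || k == n) {
    return(ew_result(F_obs, F_obs, 0, p_value = 1, p_upper = 1,
                     method = "montecarlo", n = n, k = k,
                     extra = list(n_samples = 0L,
                                  seed = if (is.null(seed)) NA_integer_ else as.integer(seed))))
  }
  theta <- solve_theta_for_k(n, k)
  fs <- numeric(n_samples)
  accepted <- 0L
  attempts <- 0L
  with_seed(seed, {
    while (accepted < n_samples) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf("conditional sampler failed: %d accepted in %d attempts (rate %.2g)",
                     accepted, attempts - 1L, accepted / (attempts - 1)),
             call. = FALSE)
      }
      cfg <- hoppe_urn_run(n, theta)
      if (length(cfg) == k) {
        accepted <- accepted + 1L
        fs[accepted] <- sum((cfg / n)^2)
      }
    }
  })
  x_le <- sum(fs <= F_obs + F_TOL)
  x_ge <- sum(fs >= F_obs - F_TOL)
  ew_result(F_obs, mean(fs), stats::sd(fs),
            p_value = (1 + x_le) / (1 + n_samples),
            p_upper = (1 + x_ge) / (1 + n_samples),
            method = "montecarlo", n = n, k = k,
            extra = list(n_samples = as.integer(n_samples),
                         n_attempts = attempts,
                         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Ewens-Watterson test, choosing enumeration when feasible
#'
#' @inheritParams ew_montecarlo_test
#' @inheritParams ew_exact_test
#' @return An `ew_result`.
#' @export
ew_test <- function(freq_table, max_partitions = 5e5, n_samples = 2000,
                    seed = NULL) {
  tryCatch(
    ew_exact_test(freq_table, max_partitions = max_partitions),
    hlapop_enumeration_overflow = function(e) {
      ew_montecarlo_test(freq_table, n_samples = n_samples, seed = seed)
    }
  )
}
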