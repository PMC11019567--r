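# Synthetic population generator with known ground truth.
#
# Genotypes are built by random union of gametes: 2n haplotypes are drawn
# from the true haplotype frequencies and paired at random, so multi-locus
# genotypes are in Hardy-Weinberg proportions at the haplotype level when
# the deviation parameter is zero. A deviation f in [0, 1) makes each
# individual, with probability f, a "homozygote duplication" (one haplotype
# drawn and paired with itself), which is the classical inbreeding-mixture
# model: for a biallelic locus the expected heterozygote proportion is
# 2pq(1 - f). Untyped markers are injected independently per allele field
# at the stated missing rate.

#' Specify a synthetic population
#'
#' Ground truth is given either as explicit multi-locus haplotype
#' frequencies (`haplotype_freqs`, names `~`-joined in locus order) or as
#' independent per-locus allele frequencies (`allele_freqs`), in which case
#' haplotype frequencies are the products of the per-locus frequencies
#' (linkage equilibrium).
#'
#' @param loci Character vector of locus names.
#' @param haplotype_freqs Named numeric vector summing to 1, or `NULL`.
#' @param allele_freqs List (one element per locus) of named numeric
#'   vectors summing to 1, or `NULL`.
#' @param n_individuals Number of diploid individuals to draw.
#' @param inbreeding Hardy-Weinberg deviation parameter f in `[0, 1)`.
#' @param missing_rate Per-allele-field probability of an untyped marker.
#' @param seed Integer seed.
#' @param name Population name recorded in the dataset metadata.
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(loci, haplotype_freqs = NULL, allele_freqs = NULL,
                            n_individuals = 100L, inbreeding = 0,
                            missing_rate = 0, seed = NULL,
                            name = "synthetic") {
  if (length(loci) == 0L) stop("at least one locus required", call. = FALSE)
  if (is.null(haplotype_freqs) == is.null(allele_freqs)) {
    stop("give exactly one of haplotype_freqs or allele_freqs", call. = FALSE)
  }
  if (!is.null(allele_freqs)) {
    if (length(allele_freqs) != length(loci)) {
      stop("allele_freqs must have one element per locus", call. = FALSE)
    }
    for (af in allele_freqs) {
      if (length(af) == 0L) stop("degenerate spec: locus with zero alleles", call. = FALSE)
      if (is.null(names(af)) || abs(sum(af) - 1) > 1e-9) {
        stop("allele frequencies must be named and sum to 1", call. = FALSE)
      }
    }
    # expand to haplotype frequencies under linkage equilibrium
    grids <- expand.grid(lapply(allele_freqs, names),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fr <- Reduce(`*`, lapply(seq_along(allele_freqs), function(j) {
      allele_freqs[[j]][grids[[j]]]
    }))
    haplotype_freqs <- stats::setNames(as.numeric(fr),
                                       apply(grids, 1L, paste, collapse = "~"))
  } else {
    if (length(haplotype_freqs) == 0L) {
      stop("degenerate spec: zero haplotypes", call. = FALSE)
    }
    if (is.null(names(haplotype_freqs)) || abs(sum(haplotype_freqs) - 1) > 1e-9) {
      stop("haplotype frequencies must be named and sum to 1", call. = FALSE)
    }
    n_parts <- lengths(strsplit(names(haplotype_freqs), "~", fixed = TRUE))
    if (any(n_parts != length(loci))) {
      stop("haplotype names must have one allele per locus", call. = FALSE)
    }
  }
  if (inbreeding < 0 || inbreeding >= 1) {
    stop("inbreeding must be in [0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(loci = loci, haplotype_freqs = haplotype_freqs,
         n_individuals = as.integer(n_individuals),
         inbreeding = inbreeding, missing_rate = missing_rate,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         name = name),
    class = "simulation_spec"
  )
}

#' Draw a synthetic population dataset
#'
#' Samples a `pop_dataset` from a [simulation_spec()] and returns it with
#' its ground truth. A fixed seed reproduces the dataset exactly.
#'
#' @param spec A `simulation_spec`.
#' @param seed Optional integer overriding the seed in the spec.
#' @return List with `dataset` (a `pop_dataset`) and `truth` (true
#'   haplotype frequencies, per-locus allele frequency marginals, the
#'   deviation parameter and the gamete draws behind the data).
#' @export
sample_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(seed)) seed <- if (is.na(spec$seed)) NULL else spec$seed
  hf <- spec$haplotype_freqs
  hap_mat <- do.call(rbind, strsplit(names(hf), "~", fixed = TRUE))
  n <- spec$n_individuals
  L <- length(spec$loci)

  draws <- with_seed(seed, {
    dup <- stats::runif(n) < spec$inbreeding
    g1 <- sample.int(length(hf), n, replace = TRUE, prob = hf)
    g2 <- sample.int(length(hf), n, replace = TRUE, prob = hf)
    g2[dup] <- g1[dup]
    miss1 <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    miss2 <- matrix(stats::runif(n * L) < spec$missing_rate, n, L)
    list(g1 = g1, g2 = g2, dup = dup, miss1 = miss1, miss2 = miss2)
  })
  a1 <- hap_mat[draws$g1, , drop = FALSE]
  a2 <- hap_mat[draws$g2, , drop = FALSE]
  a1[draws$miss1] <- NA_character_
  a2[draws$miss2] <- NA_character_

  dataset <- new_pop_dataset(c(name = spec$name), spec$loci, a1, a2)
  # per-locus marginal allele frequencies implied by the haplotype truth
  marginals <- lapply(seq_len(L), function(j) {
    tapply(hf, hap_mat[, j], sum)
  })
  names(marginals) <- spec$loci
  list(dataset = dataset,
       truth = list(haplotype_freqs = hf,
                    allele_freqs = marginals,
                    inbreeding = spec$inbreeding,
                    missing_rate = spec$missing_rate,
                    gametes = cbind(draws$g1, draws$g2)))
}
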