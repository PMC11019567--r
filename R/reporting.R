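# Per-population reporting: the analysis driver, machine-readable XML and
# human-readable text outputs, and the cross-population TSV aggregator.
#
# The XML vocabulary is defined by this package (see the methods vignette):
# one <populationReport> document per population, with one <locus> block
# per locus carrying the per-locus statistics that were requested, one
# <haplotypeEstimate> block per requested locus set, and one <ldPair>
# block per requested pair. Numeric attributes are serialized at full
# double precision; frequency-like values additionally carry a 6
# significant digit "display" attribute.

#' Run the configured analyses on one population
#'
#' Applies the custom binning filter (if the configuration defines one) and
#' then runs each analysis whose section appears in the configuration:
#' `[HardyWeinberg]` (chi-square with lumping), `[HardyWeinbergExact]`
#' (enumeration with Monte Carlo fallback), `[EwensWatterson]`,
#' `[Haplotypes]` (EM over configured locus sets) and
#' `[LinkageDisequilibrium]` (pairwise D', Wn, ALD, optional permutation
#' test). Per-locus summaries (allele and genotype counts, homozygosity)
#' are always computed.
#'
#' Recognized keys: `[Summary] individualGenotypes`; `[HardyWeinberg]
#' lumpBelow`; `[HardyWeinbergExact] method|numSamples|maxTables|seed`;
#' `[EwensWatterson] method|numSamples|maxPartitions|seed`; `[Haplotypes]
#' lociSets|tol|maxIter|restarts|seed` (locus sets are colon-joined, comma
#' separated, or `all-pairs`); `[LinkageDisequilibrium]
#' pairs|permutations|seed`.
#'
#' @param dataset A `pop_dataset`.
#' @param config An `analysis_config` from [parse_config()].
#' @param seed Master integer seed; per-analysis seeds are derived from it
#'   unless a section supplies its own `seed` key.
#' @return A `population_report`.
#' @export
run_population_analysis <- function(dataset, config, seed = NULL) {
  stopifnot(inherits(dataset, "pop_dataset"), inherits(config, "analysis_config"))
  dataset <- apply_binning(dataset, config$binning)
  sec <- names(config$sections)
  notes <- character(0)

  section_seed <- function(section, offset) {
    s <- config_get(config, section, "seed")
    if (!is.null(s)) as.integer(s) else derive_seed(seed, offset)
  }

  summary_blocks <- list()
  for (locus in dataset$loci) {
    blk <- tryCatch({
      af <- count_alleles(dataset, locus)
      gt <- genotype_counts(dataset, locus)
      list(afreq = af, gt = gt, f_obs = observed_homozygosity(af))
    }, error = function(e) {
      notes <<- c(notes, sprintf("locus %s: %s", locus, conditionMessage(e)))
      NULL
    })
    summary_blocks[[locus]] <- blk
  }

  hwe_chisq_blocks <- NULL
  if ("HardyWeinberg" %in% sec) {
    lump <- as.numeric(config_get(config, "HardyWeinberg", "lumpBelow", "5"))
    hwe_chisq_blocks <- list()
    for (locus in dataset$loci) {
      blk <- summary_blocks[[locus]]
      if (is.null(blk)) next
      res <- tryCatch(hwe_chisq(blk$gt, lump_below = lump), error = function(e) {
        notes <<- c(notes, sprintf("HardyWeinberg at %s: %s", locus,
                                   conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) hwe_chisq_blocks[[locus]] <- res
    }
  }

  hwe_exact_blocks <- NULL
  if ("HardyWeinbergExact" %in% sec) {
    method <- config_get(config, "HardyWeinbergExact", "method", "auto")
    n_samples <- as.integer(config_get(config, "HardyWeinbergExact", "numSamples", "10000"))
    max_tables <- as.numeric(config_get(config, "HardyWeinbergExact", "maxTables", "50000"))
    hwe_exact_blocks <- list()
    for (li in seq_along(dataset$loci)) {
      locus <- dataset$loci[li]
      blk <- summary_blocks[[locus]]
      if (is.null(blk) || blk$afreq$k < 2L) {
        if (!is.null(blk)) {
          notes <- c(notes, sprintf("HardyWeinbergExact at %s: monomorphic locus", locus))
        }
        next
      }
      s <- section_seed("HardyWeinbergExact", 100L + li)
      res <- switch(method,
        enumeration = tryCatch(
          hwe_exact_enumeration(blk$gt, max_tables = max_tables),
          hlapop_enumeration_overflow = function(e) {
            notes <<- c(notes, sprintf("HardyWeinbergExact at %s: %s", locus,
                                       conditionMessage(e)))
            NULL
          }),
        montecarlo = hwe_exact_montecarlo(blk$gt, n_samples = n_samples, seed = s),
        hwe_exact_test(blk$gt, max_tables = max_tables,
                       n_samples = n_samples, seed = s))
      if (!is.null(res)) hwe_exact_blocks[[locus]] <- res
    }
  }

  ew_blocks <- NULL
  if ("EwensWatterson" %in% sec) {
    method <- config_get(config, "EwensWatterson", "method", "auto")
    n_samples <- as.integer(config_get(config, "EwensWatterson", "numSamples", "2000"))
    max_parts <- as.numeric(config_get(config, "EwensWatterson", "maxPartitions", "500000"))
    ew_blocks <- list()
    for (li in seq_along(dataset$loci)) {
      locus <- dataset$loci[li]
      blk <- summary_blocks[[locus]]
      if (is.null(blk)) next
      s <- section_seed("EwensWatterson", 200L + li)
      res <- switch(method,
        enumeration = ew_exact_test(blk$afreq, max_partitions = max_parts),
        montecarlo = ew_montecarlo_test(blk$afreq, n_samples = n_samples, seed = s),
        ew_test(blk$afreq, max_partitions = max_parts,
                n_samples = n_samples, seed = s))
      ew_blocks[[locus]] <- res
    }
  }

  hap_blocks <- NULL
  hap_sets <- list()
  if ("Haplotypes" %in% sec) {
    sets_str <- config_get(config, "Haplotypes", "lociSets", "all-pairs")
    hap_sets <- parse_locus_sets(sets_str, dataset$loci)
    tol <- as.numeric(config_get(config, "Haplotypes", "tol", "1e-7"))
    max_iter <- as.integer(config_get(config, "Haplotypes", "maxIter", "1000"))
    restarts <- as.integer(config_get(config, "Haplotypes", "restarts", "1"))
    hap_blocks <- list()
    for (si in seq_along(hap_sets)) {
      loci_set <- hap_sets[[si]]
      key <- paste(loci_set, collapse = ":")
      s <- section_seed("Haplotypes", 300L + si)
      res <- tryCatch(
        estimate_haplotypes(dataset, loci_set, tol = tol, max_iter = max_iter,
                            n_restarts = restarts, seed = s),
        error = function(e) {
          notes <<- c(notes, sprintf("Haplotypes %s: %s", key, conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) hap_blocks[[key]] <- res
    }
  }

  ld_blocks <- NULL
  if ("LinkageDisequilibrium" %in% sec) {
    pairs_str <- config_get(config, "LinkageDisequilibrium", "pairs", "all")
    pairs <- parse_locus_pairs(pairs_str, dataset$loci)
    n_perm <- as.integer(config_get(config, "LinkageDisequilibrium", "permutations", "0"))
    ld_blocks <- list()
    for (pi in seq_along(pairs)) {
      pr <- pairs[[pi]]
      key <- paste(pr, collapse = ":")
      s <- section_seed("LinkageDisequilibrium", 400L + pi)
      res <- tryCatch(
        ld_pair(dataset, pr[1], pr[2], n_permutations = n_perm, seed = s),
        error = function(e) {
          notes <<- c(notes, sprintf("LinkageDisequilibrium %s: %s", key,
                                     conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) ld_blocks[[key]] <- res
    }
  }

  structure(
    list(metadata = dataset$metadata,
         loci = dataset$loci,
         requested = intersect(sec, c("HardyWeinberg", "HardyWeinbergExact",
                                      "EwensWatterson", "Haplotypes",
                                      "LinkageDisequilibrium")),
         individual_genotypes =
           tolower(config_get(config, "Summary", "individualGenotypes", "false")) %in%
             c("true", "1", "yes"),
         summary = summary_blocks,
         hwe_chisq = hwe_chisq_blocks,
         hwe_exact = hwe_exact_blocks,
         ew = ew_blocks,
         haplotypes = hap_blocks,
         ld = ld_blocks,
         notes = notes),
    class = "population_report"
  )
}

#' @keywords internal
#' @noRd
parse_locus_sets <- function(sets_str, loci) {
  if (identical(trimws(sets_str), "all-pairs")) {
    if (length(loci) < 2L) return(list())
    cmb <- utils::combn(loci, 2L, simplify = FALSE)
    return(cmb)
  }
  sets <- strsplit(strsplit(sets_str, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  lapply(sets, trimws)
}

#' @keywords internal
#' @noRd
parse_locus_pairs <- function(pairs_str, loci) {
  if (identical(trimws(pairs_str), "all")) {
    if (length(loci) < 2L) return(list())
    return(utils::combn(loci, 2L, simplify = FALSE))
  }
  out <- parse_locus_sets(pairs_str, loci)
  if (any(lengths(out) != 2L)) {
    stop("LD pairs must name exactly two loci each", call. = FALSE)
  }
  out
}

# ---------------------------------------------------------------------------
# XML output

num_attr <- function(x) fmt_full(as.numeric(x))

add_freq_attrs <- function(node, frequency) {
  xml2::xml_set_attr(node, "frequency", num_attr(frequency))
  xml2::xml_set_attr(node, "display", fmt_sig6(frequency))
}

#' Write a population report as XML
#'
#' One XML document per population. Numeric values are serialized at full
#' double precision (frequencies also carry a 6-significant-digit `display`
#' attribute) so that [read_population_xml()] round-trips every numeric
#' field.
#'
#' @param report A `population_report`.
#' @param path Output path (conventionally `<population>.xml`).
#' @return `path`, invisibly.
#' @export
write_population_xml <- function(report, path) {
  stopifnot(inherits(report, "population_report"))
  doc <- xml2::xml_new_root("populationReport",
                            name = report$metadata["name"] %||% "unnamed")
  meta <- xml2::xml_add_child(doc, "metadata")
  for (key in names(report$metadata)) {
    xml2::xml_add_child(meta, "field", report$metadata[[key]], key = key)
  }

  for (locus in report$loci) {
    blk <- report$summary[[locus]]
    if (is.null(blk)) next
    ln <- xml2::xml_add_child(doc, "locus", name = locus)
    af <- blk$afreq
    ac <- xml2::xml_add_child(ln, "alleleCounts",
                              nGametes = as.character(af$n_gametes),
                              nIndividuals = as.character(af$n_individuals),
                              nExcluded = as.character(af$n_excluded),
                              k = as.character(af$k))
    for (i in seq_along(af$counts)) {
      a <- xml2::xml_add_child(ac, "allele",
                               name = names(af$counts)[i],
                               count = as.character(af$counts[i]))
      add_freq_attrs(a, af$freqs[i])
    }
    gc <- xml2::xml_add_child(ln, "genotypeCounts",
                              nIndividuals = as.character(blk$gt$n_individuals),
                              show = if (report$individual_genotypes) "true" else "false")
    for (i in seq_along(blk$gt$counts)) {
      xml2::xml_add_child(gc, "genotype",
                          name = names(blk$gt$counts)[i],
                          count = as.character(blk$gt$counts[i]))
    }
    xml2::xml_add_child(ln, "homozygosity", observed = num_attr(blk$f_obs))

    hw <- report$hwe_chisq[[locus]]
    if (!is.null(hw)) {
      xml2::xml_add_child(ln, "hardyWeinbergChiSq",
                          chisq = num_attr(hw$chisq),
                          df = as.character(hw$df),
                          pvalue = num_attr(hw$pvalue),
                          lumpBelow = num_attr(hw$lump_below))
    }
    hx <- report$hwe_exact[[locus]]
    if (!is.null(hx)) {
      xml2::xml_add_child(ln, "hardyWeinbergExact",
                          method = hx$method,
                          pOverall = num_attr(hx$p_overall),
                          pHetExcess = num_attr(hx$p_het_excess),
                          pHetDeficit = num_attr(hx$p_het_deficit),
                          nTables = as.character(hx$n_tables_enumerated %||% NA_integer_),
                          nSteps = as.character(hx$n_steps %||% NA_integer_),
                          seed = as.character(hx$seed))
    }
    ew <- report$ew[[locus]]
    if (!is.null(ew)) {
      xml2::xml_add_child(ln, "ewensWatterson",
                          method = ew$method,
                          fObs = num_attr(ew$F_obs),
                          eF = num_attr(ew$E_F),
                          sdF = num_attr(ew$sd_F),
                          fNd = num_attr(ew$F_nd),
                          pValue = num_attr(ew$p_value),
                          pUpper = num_attr(ew$p_upper),
                          nSamples = as.character(ew$n_samples %||% NA_integer_),
                          seed = as.character(ew$seed))
    }
  }

  for (key in names(report$haplotypes)) {
    est <- report$haplotypes[[key]]
    hn <- xml2::xml_add_child(doc, "haplotypeEstimate",
                              loci = key,
                              nIndividuals = as.character(est$n_individuals),
                              nExcluded = as.character(est$n_excluded),
                              logLik = num_attr(est$loglik),
                              nIterations = as.character(est$n_iterations),
                              converged = if (est$converged) "true" else "false",
                              nRestarts = as.character(est$n_restarts),
                              seed = as.character(est$seed))
    tab <- haplotype_report_table(est)
    for (i in seq_len(nrow(tab))) {
      hh <- xml2::xml_add_child(hn, "haplotype",
                                name = tab$haplotype[i],
                                count = num_attr(tab$count[i]))
      add_freq_attrs(hh, tab$frequency[i])
    }
  }

  for (key in names(report$ld)) {
    res <- report$ld[[key]]
    attrs <- list(locus1 = res$locus1, locus2 = res$locus2,
                  I = as.character(res$I), J = as.character(res$J),
                  nIndividuals = as.character(res$n_individuals),
                  dprime = num_attr(res$dprime_overall),
                  wn = num_attr(res$wn),
                  ald_1_2 = num_attr(res$ald_1_2),
                  ald_2_1 = num_attr(res$ald_2_1))
    if (!is.null(res$permutation)) {
      attrs <- c(attrs, list(
        nPermutations = as.character(res$permutation$n_permutations),
        pValue = num_attr(res$permutation$p_value),
        statistic = res$permutation$statistic,
        permSeed = as.character(res$permutation$seed)))
    }
    ldn <- do.call(xml2::xml_add_child, c(list(doc, "ldPair"), attrs))
    alleles1 <- rownames(res$h)
    alleles2 <- colnames(res$h)
    for (i in seq_along(alleles1)) {
      for (j in seq_along(alleles2)) {
        if (res$h[i, j] < REPORT_FREQ_FLOOR) next
        hh <- xml2::xml_add_child(ldn, "haplotypeLD",
                                  name = paste0(alleles1[i], "~", alleles2[j]),
                                  allele1 = alleles1[i],
                                  allele2 = alleles2[j],
                                  d = num_attr(res$d[i, j]),
                                  dprime = num_attr(res$dprime[i, j]))
        add_freq_attrs(hh, res$h[i, j])
      }
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

xml_num <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v) || v == "NA") NA_real_ else as.numeric(v)
}

xml_int <- function(node, attr) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v) || v == "NA") NA_integer_ else as.integer(v)
}

#' Read a population XML document
#'
#' Parses a document written by [write_population_xml()] back into nested
#' lists with numeric fields restored at full precision. This is the input
#' format of the TSV aggregator.
#'
#' @param path Path to the XML file.
#' @return A list with `name`, `metadata`, `loci` (per-locus blocks),
#'   `haplotypes` and `ld`.
#' @export
read_population_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("malformed XML in '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (xml2::xml_name(doc) != "populationReport") {
    stop(sprintf("malformed XML in '%s': root is <%s>, expected <populationReport>",
                 path, xml2::xml_name(doc)), call. = FALSE)
  }
  meta_nodes <- xml2::xml_find_all(doc, "./metadata/field")
  metadata <- stats::setNames(xml2::xml_text(meta_nodes),
                              xml2::xml_attr(meta_nodes, "key"))

  loci <- list()
  for (ln in xml2::xml_find_all(doc, "./locus")) {
    locus <- xml2::xml_attr(ln, "name")
    ac <- xml2::xml_find_first(ln, "./alleleCounts")
    allele_nodes <- xml2::xml_find_all(ac, "./allele")
    alleles <- data.frame(
      allele = xml2::xml_attr(allele_nodes, "name"),
      count = as.integer(xml2::xml_attr(allele_nodes, "count")),
      frequency = as.numeric(xml2::xml_attr(allele_nodes, "frequency")),
      row.names = NULL)
    gc <- xml2::xml_find_first(ln, "./genotypeCounts")
    gt_nodes <- xml2::xml_find_all(gc, "./genotype")
    genotypes <- data.frame(
      genotype = xml2::xml_attr(gt_nodes, "name"),
      count = as.integer(xml2::xml_attr(gt_nodes, "count")),
      row.names = NULL)
    blk <- list(
      locus = locus,
      n_gametes = xml_int(ac, "nGametes"),
      n_individuals = xml_int(ac, "nIndividuals"),
      n_excluded = xml_int(ac, "nExcluded"),
      k = xml_int(ac, "k"),
      alleles = alleles,
      genotypes = genotypes,
      show_genotypes = identical(xml2::xml_attr(gc, "show"), "true"),
      f_obs = xml_num(xml2::xml_find_first(ln, "./homozygosity"), "observed"))
    hw <- xml2::xml_find_first(ln, "./hardyWeinbergChiSq")
    if (!inherits(hw, "xml_missing")) {
      blk$hwe_chisq <- list(chisq = xml_num(hw, "chisq"), df = xml_int(hw, "df"),
                            pvalue = xml_num(hw, "pvalue"),
                            lump_below = xml_num(hw, "lumpBelow"))
    }
    hx <- xml2::xml_find_first(ln, "./hardyWeinbergExact")
    if (!inherits(hx, "xml_missing")) {
      blk$hwe_exact <- list(method = xml2::xml_attr(hx, "method"),
                            p_overall = xml_num(hx, "pOverall"),
                            p_het_excess = xml_num(hx, "pHetExcess"),
                            p_het_deficit = xml_num(hx, "pHetDeficit"),
                            n_tables = xml_int(hx, "nTables"),
                            n_steps = xml_int(hx, "nSteps"))
    }
    ew <- xml2::xml_find_first(ln, "./ewensWatterson")
    if (!inherits(ew, "xml_missing")) {
      blk$ew <- list(method = xml2::xml_attr(ew, "method"),
                     F_obs = xml_num(ew, "fObs"), E_F = xml_num(ew, "eF"),
                     sd_F = xml_num(ew, "sdF"), F_nd = xml_num(ew, "fNd"),
                     p_value = xml_num(ew, "pValue"),
                     p_upper = xml_num(ew, "pUpper"))
    }
    loci[[locus]] <- blk
  }

  haplotypes <- list()
  for (hn in xml2::xml_find_all(doc, "./haplotypeEstimate")) {
    key <- xml2::xml_attr(hn, "loci")
    hap_nodes <- xml2::xml_find_all(hn, "./haplotype")
    haplotypes[[key]] <- list(
      loci = strsplit(key, ":", fixed = TRUE)[[1]],
      n_individuals = xml_int(hn, "nIndividuals"),
      n_excluded = xml_int(hn, "nExcluded"),
      loglik = xml_num(hn, "logLik"),
      n_iterations = xml_int(hn, "nIterations"),
      converged = identical(xml2::xml_attr(hn, "converged"), "true"),
      table = data.frame(
        haplotype = xml2::xml_attr(hap_nodes, "name"),
        frequency = as.numeric(xml2::xml_attr(hap_nodes, "frequency")),
        count = as.numeric(xml2::xml_attr(hap_nodes, "count")),
        row.names = NULL))
  }

  ld <- list()
  for (ldn in xml2::xml_find_all(doc, "./ldPair")) {
    l1 <- xml2::xml_attr(ldn, "locus1")
    l2 <- xml2::xml_attr(ldn, "locus2")
    hap_nodes <- xml2::xml_find_all(ldn, "./haplotypeLD")
    rec <- list(
      locus1 = l1, locus2 = l2,
      I = xml_int(ldn, "I"), J = xml_int(ldn, "J"),
      n_individuals = xml_int(ldn, "nIndividuals"),
      dprime = xml_num(ldn, "dprime"),
      wn = xml_num(ldn, "wn"),
      ald_1_2 = xml_num(ldn, "ald_1_2"),
      ald_2_1 = xml_num(ldn, "ald_2_1"),
      haplotypes = data.frame(
        haplotype = xml2::xml_attr(hap_nodes, "name"),
        frequency = as.numeric(xml2::xml_attr(hap_nodes, "frequency")),
        d = as.numeric(xml2::xml_attr(hap_nodes, "d")),
        dprime = as.numeric(xml2::xml_attr(hap_nodes, "dprime")),
        row.names = NULL))
    if (!is.na(xml2::xml_attr(ldn, "nPermutations"))) {
      rec$permutation <- list(
        n_permutations = xml_int(ldn, "nPermutations"),
        p_value = xml_num(ldn, "pValue"),
        statistic = xml2::xml_attr(ldn, "statistic"))
    }
    ld[[paste(l1, l2, sep = ":")]] <- rec
  }

  list(name = xml2::xml_attr(doc, "name"), metadata = metadata,
       loci = loci, haplotypes = haplotypes, ld = ld)
}

# ---------------------------------------------------------------------------
# Text report

#' Render a population report as plain text
#'
#' Fixed-width tables suitable for publication drafts. The LD section lays
#' out the columns `D'`, `Wn`, `ALD_1_2`, `ALD_2_1`, with `# permu` and
#' `p-value` appended only when a permutation test was run. Haplotype names
#' use the GL String `~` separator.
#'
#' @param report A `population_report`.
#' @param path Optional output path; when `NULL` the text is only returned.
#' @return The report text as a character vector of lines, invisibly when
#'   `path` is given.
#' @export
write_text_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "population_report"))
  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))
  push("Population: ", report$metadata["name"] %||% "<unnamed>")
  for (key in setdiff(names(report$metadata), "name")) {
    push(key, ": ", report$metadata[[key]])
  }
  push("Loci: ", paste(report$loci, collapse = ", "))
  push("")

  push("I. Single-locus statistics")
  push(strrep("=", 40))
  for (locus in report$loci) {
    blk <- report$summary[[locus]]
    if (is.null(blk)) next
    af <- blk$afreq
    push("")
    push("Locus: ", locus)
    push(sprintf("  gametes: %d  untyped individuals: %d  distinct alleles (k): %d",
                 af$n_gametes, af$n_excluded, af$k))
    push(sprintf("  observed homozygosity F: %s", fmt_sig6(blk$f_obs)))
    push(sprintf("  %-22s %8s %10s", "Allele", "Count", "Frequency"))
    for (i in seq_along(af$counts)) {
      push(sprintf("  %-22s %8d %10s", names(af$counts)[i], af$counts[i],
                   fmt_sig6(af$freqs[i])))
    }
    if (report$individual_genotypes) {
      push(sprintf("  %-30s %8s", "Genotype", "Count"))
      for (i in seq_along(blk$gt$counts)) {
        push(sprintf("  %-30s %8d", names(blk$gt$counts)[i], blk$gt$counts[i]))
      }
    }
    hw <- report$hwe_chisq[[locus]]
    if (!is.null(hw)) {
      push(sprintf("  HardyWeinberg chi-square: chisq = %s, df = %d, p = %s",
                   fmt_sig6(hw$chisq), hw$df, fmt_sig6(hw$pvalue)))
    }
    hx <- report$hwe_exact[[locus]]
    if (!is.null(hx)) {
      lab <- if (hx$method == "enumeration") {
        sprintf("full enumeration, %d tables", hx$n_tables_enumerated)
      } else {
        sprintf("monte-carlo, %d samples", hx$n_steps)
      }
      push(sprintf("  HardyWeinberg exact (%s): p = %s", lab, fmt_sig6(hx$p_overall)))
      push(sprintf("    heterozygote excess p = %s, deficit p = %s",
                   fmt_sig6(hx$p_het_excess), fmt_sig6(hx$p_het_deficit)))
    }
    ew <- report$ew[[locus]]
    if (!is.null(ew)) {
      push(sprintf("  Ewens-Watterson (%s): F = %s, E[F] = %s, Fnd = %s, p = %s",
                   ew$method, fmt_sig6(ew$F_obs), fmt_sig6(ew$E_F),
                   fmt_sig6(ew$F_nd), fmt_sig6(ew$p_value)))
    }
  }

  if (!is.null(report$haplotypes) && length(report$haplotypes) > 0L) {
    push("")
    push("II. Haplotype estimation (EM)")
    push(strrep("=", 40))
    for (key in names(report$haplotypes)) {
      est <- report$haplotypes[[key]]
      push("")
      push(sprintf("Loci: %s  (n = %d, excluded = %d)",
                   gsub(":", "~", key, fixed = TRUE),
                   est$n_individuals, est$n_excluded))
      push(sprintf("  log-likelihood = %s after %d iterations (%s)",
                   fmt_sig6(est$loglik), est$n_iterations,
                   if (est$converged) "converged" else "not converged"))
      tab <- haplotype_report_table(est)
      push(sprintf("  %-34s %10s %10s", "Haplotype", "Frequency", "Count"))
      for (i in seq_len(nrow(tab))) {
        push(sprintf("  %-34s %10s %10s", tab$haplotype[i],
                     fmt_sig6(tab$frequency[i]), fmt_sig6(tab$count[i])))
      }
    }
  }

  if (!is.null(report$ld) && length(report$ld) > 0L) {
    push("")
    push("III. Pairwise linkage disequilibrium")
    push(strrep("=", 40))
    any_perm <- any(vapply(report$ld, function(x) !is.null(x$permutation), TRUE))
    header <- sprintf("%-18s %9s %9s %9s %9s", "Locus pair", "D'", "Wn",
                      "ALD_1_2", "ALD_2_1")
    if (any_perm) header <- paste0(header, sprintf(" %9s %9s", "# permu", "p-value"))
    push(header)
    for (key in names(report$ld)) {
      res <- report$ld[[key]]
      row <- sprintf("%-18s %9s %9s %9s %9s",
                     paste0(res$locus1, ":", res$locus2),
                     fmt_sig6(res$dprime_overall), fmt_sig6(res$wn),
                     fmt_sig6(res$ald_1_2), fmt_sig6(res$ald_2_1))
      if (any_perm) {
        if (!is.null(res$permutation)) {
          row <- paste0(row, sprintf(" %9d %9s", res$permutation$n_permutations,
                                     fmt_sig6(res$permutation$p_value)))
        } else {
          row <- paste0(row, sprintf(" %9s %9s", "-", "-"))
        }
      }
      push(row)
    }
  }

  if (length(report$notes) > 0L) {
    push("")
    push("Notes:")
    for (nt in report$notes) push("  - ", nt)
  }
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

# ---------------------------------------------------------------------------
# TSV aggregation (popmeta-style)

tsv_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.10g", x))
}

ihwg_cols <- function(metadata) {
  list(pop.label = unname(metadata["label"] %||% NA_character_),
       region = unname(metadata["region"] %||% NA_character_),
       ethnicity = unname(metadata["ethnicity"] %||% NA_character_))
}

#' Aggregate population XML documents into TSV meta-analysis files
#'
#' Reads one or more per-population XML documents and emits the family of
#' tab-separated files whose data exist: `1-locus-summary.tsv`,
#' `1-locus-allele.tsv`, `1-locus-genotype.tsv` (only when individual
#' genotype statistics were requested), `1-locus-hardyweinberg.tsv`,
#' `2-locus-summary.tsv`, `2-locus-haplo.tsv` and, for every haplotype
#' length n of 3 or more that was estimated, `n-locus-summary.tsv` /
#' `n-locus-haplo.tsv` (e.g. `5-locus-haplo.tsv`). Files are dynamically
#' generated: no empty-but-headered file is ever written. Permutation
#' columns appear in `2-locus-summary.tsv` only when a permutation test was
#' run. TSVs are tab-separated with a header row, LF line endings and `NA`
#' for undefined values.
#'
#' @param xml_paths Character vector of XML document paths.
#' @param outputdir Output directory (created if needed).
#' @param prefix Optional filename prefix (e.g. `"run1_"`).
#' @param enable_ihwg Include the workshop metadata columns (`pop.label`,
#'   `region`, `ethnicity`, populated from .pop metadata)? Default off.
#' @return Character vector of files written (full paths), invisibly.
#' @export
aggregate_tsv <- function(xml_paths, outputdir = ".", prefix = "",
                          enable_ihwg = FALSE) {
  if (length(xml_paths) == 0L) stop("no XML documents supplied", call. = FALSE)
  docs <- lapply(xml_paths, read_population_xml)
  if (!dir.exists(outputdir)) dir.create(outputdir, recursive = TRUE)

  base_cols <- function(doc) {
    c(list(pop = doc$name), if (enable_ihwg) ihwg_cols(doc$metadata))
  }
  rows1_summary <- list(); rows1_allele <- list(); rows1_geno <- list()
  rows1_hw <- list()
  rows2_summary <- list(); rows2_haplo <- list()
  rowsn_summary <- list(); rowsn_haplo <- list()
  any_perm <- FALSE

  for (doc in docs) {
    bc <- base_cols(doc)
    for (blk in doc$loci) {
      ewp <- blk$ew
      hwc <- blk$hwe_chisq
      rows1_summary[[length(rows1_summary) + 1L]] <- c(bc, list(
        locus = blk$locus, n.gametes = blk$n_gametes,
        n.typed = blk$n_individuals, n.untyped = blk$n_excluded,
        k = blk$k, f.obs = tsv_num(blk$f_obs),
        hw.chisq = tsv_num(hwc$chisq %||% NA_real_),
        hw.chisq.df = hwc$df %||% NA_integer_,
        hw.chisq.pvalue = tsv_num(hwc$pvalue %||% NA_real_),
        ew.e.f = tsv_num(ewp$E_F %||% NA_real_),
        ew.f.nd = tsv_num(ewp$F_nd %||% NA_real_),
        ew.pvalue = tsv_num(ewp$p_value %||% NA_real_)))
      for (i in seq_len(nrow(blk$alleles))) {
        rows1_allele[[length(rows1_allele) + 1L]] <- c(bc, list(
          locus = blk$locus, allele = blk$alleles$allele[i],
          allele.count = blk$alleles$count[i],
          allele.freq = tsv_num(blk$alleles$frequency[i])))
      }
      if (isTRUE(blk$show_genotypes)) {
        for (i in seq_len(nrow(blk$genotypes))) {
          rows1_geno[[length(rows1_geno) + 1L]] <- c(bc, list(
            locus = blk$locus, genotype = blk$genotypes$genotype[i],
            genotype.count = blk$genotypes$count[i]))
        }
      }
      if (!is.null(blk$hwe_exact)) {
        hx <- blk$hwe_exact
        rows1_hw[[length(rows1_hw) + 1L]] <- c(bc, list(
          locus = blk$locus, k = blk$k,
          hw.chisq.pvalue = tsv_num(hwc$pvalue %||% NA_real_),
          hw.exact.method = hx$method,
          hw.exact.pvalue = tsv_num(hx$p_overall),
          hw.het.excess.pvalue = tsv_num(hx$p_het_excess),
          hw.het.deficit.pvalue = tsv_num(hx$p_het_deficit)))
      }
    }

    pair_keys <- union(names(doc$haplotypes)[
      vapply(doc$haplotypes, function(h) length(h$loci) == 2L, TRUE)],
      names(doc$ld))
    for (key in pair_keys) {
      est <- doc$haplotypes[[key]]
      ldr <- doc$ld[[key]]
      loci_pair <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (!is.null(ldr$permutation)) any_perm <- TRUE
      rows2_summary[[length(rows2_summary) + 1L]] <- c(bc, list(
        locus1 = loci_pair[1], locus2 = loci_pair[2],
        n.individuals = (est$n_individuals %||% ldr$n_individuals) %||% NA_integer_,
        loglik = tsv_num(est$loglik %||% NA_real_),
        converged = if (is.null(est)) NA else est$converged,
        ld.dprime = tsv_num(ldr$dprime %||% NA_real_),
        ld.wn = tsv_num(ldr$wn %||% NA_real_),
        ald.1.2 = tsv_num(ldr$ald_1_2 %||% NA_real_),
        ald.2.1 = tsv_num(ldr$ald_2_1 %||% NA_real_),
        permu.n = ldr$permutation$n_permutations %||% NA_integer_,
        permu.pvalue = tsv_num(ldr$permutation$p_value %||% NA_real_)))
      # haplotype rows: prefer the EM block, annotated with per-haplotype LD
      hap_tab <- if (!is.null(est)) est$table else
        ldr$haplotypes[, c("haplotype", "frequency")]
      if (!is.null(hap_tab) && nrow(hap_tab) > 0L) {
        ld_lookup <- if (!is.null(ldr)) ldr$haplotypes else NULL
        for (i in seq_len(nrow(hap_tab))) {
          hname <- hap_tab$haplotype[i]
          li <- if (!is.null(ld_lookup)) match(hname, ld_lookup$haplotype) else NA_integer_
          rows2_haplo[[length(rows2_haplo) + 1L]] <- c(bc, list(
            locus1 = loci_pair[1], locus2 = loci_pair[2],
            haplotype = hname,
            haplo.freq = tsv_num(hap_tab$frequency[i]),
            haplo.count = tsv_num(hap_tab$count[i] %||% NA_real_),
            ld.d = tsv_num(if (is.na(li)) NA_real_ else ld_lookup$d[li]),
            ld.dprime = tsv_num(if (is.na(li)) NA_real_ else ld_lookup$dprime[li])))
        }
      }
    }

    for (key in names(doc$haplotypes)) {
      est <- doc$haplotypes[[key]]
      L <- length(est$loci)
      if (L <= 2L) next
      rowsn_summary[[as.character(L)]] <- c(rowsn_summary[[as.character(L)]], list(c(bc, list(
        loci = key, n.loci = L,
        n.individuals = est$n_individuals,
        loglik = tsv_num(est$loglik),
        n.haplotypes = nrow(est$table),
        converged = est$converged))))
      hrows <- lapply(seq_len(nrow(est$table)), function(i) {
        c(bc, list(loci = key, haplotype = est$table$haplotype[i],
                   haplo.freq = tsv_num(est$table$frequency[i]),
                   haplo.count = tsv_num(est$table$count[i])))
      })
      rowsn_haplo[[as.character(L)]] <- c(rowsn_haplo[[as.character(L)]], hrows)
    }
  }

  written <- character(0)
  emit <- function(rows, fname) {
    if (length(rows) == 0L) return(invisible())
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE, check.names = FALSE)
    }))
    path <- file.path(outputdir, paste0(prefix, fname))
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", eol = "\n")
    written <<- c(written, path)
    invisible()
  }

  if (!any_perm) {
    rows2_summary <- lapply(rows2_summary, function(r) {
      r$permu.n <- NULL; r$permu.pvalue <- NULL; r
    })
  }

  emit(rows1_summary, "1-locus-summary.tsv")
  emit(rows1_allele, "1-locus-allele.tsv")
  emit(rows1_geno, "1-locus-genotype.tsv")
  emit(rows1_hw, "1-locus-hardyweinberg.tsv")
  emit(rows2_summary, "2-locus-summary.tsv")
  emit(rows2_haplo, "2-locus-haplo.tsv")
  for (Lc in names(rowsn_summary)) {
    emit(rowsn_summary[[Lc]], sprintf("%s-locus-summary.tsv", Lc))
  }
  for (Lc in names(rowsn_haplo)) {
    emit(rowsn_haplo[[Lc]], sprintf("%s-locus-haplo.tsv", Lc))
  }
  invisible(written)
}
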