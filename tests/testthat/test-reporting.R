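# Report assembly, XML round trip, text layout, and TSV aggregation.

make_pipeline_fixture <- function(dir, permutations = 0, loci_sets = "A:B",
                                  n = 30, seeds = c(1001, 1002),
                                  extra_cfg = character(0)) {
  af <- list(c("01:01" = 0.5, "02:01" = 0.3, "03:01" = 0.2),
             c("07:02" = 0.6, "08:01" = 0.4))
  for (i in seq_along(seeds)) {
    spec <- simulation_spec(c("A", "B"), allele_freqs = af, n_individuals = n,
                            seed = seeds[i], name = paste0("pop", i))
    write_pop_file(sample_population(spec)$dataset,
                   file.path(dir, paste0("pop", i, ".pop")))
  }
  cfg <- file.path(dir, "cfg.ini")
  writeLines(standard_config_lines(permutations = permutations,
                                   loci_sets = loci_sets, extra = extra_cfg), cfg)
  cfg
}

run_one_report <- function(dir, permutations = 0, loci_sets = "A:B",
                           extra_cfg = character(0)) {
  cfg_path <- make_pipeline_fixture(dir, permutations, loci_sets,
                                    seeds = 1001, extra_cfg = extra_cfg)
  config <- parse_config(cfg_path)
  dataset <- parse_pop_file(file.path(dir, "pop1.pop"))
  run_population_analysis(dataset, config, seed = 17)
}

test_that("reports contain exactly the requested analysis blocks", {
  dir <- withr::local_tempdir()
  cfg <- parse_config(write_config(c("[HardyWeinberg]", "lumpBelow = 5")))
  spec <- simulation_spec("A", allele_freqs = list(c(x = 0.6, y = 0.4)),
                          n_individuals = 20, seed = 3, name = "only-hwe")
  report <- run_population_analysis(sample_population(spec)$dataset, cfg)
  expect_equal(report$requested, "HardyWeinberg")
  expect_false(is.null(report$hwe_chisq[["A"]]))
  expect_null(report$hwe_exact)
  expect_null(report$ew)
  expect_null(report$haplotypes)
  expect_null(report$ld)
  # and the XML mirrors that
  xml_path <- file.path(dir, "r.xml")
  write_population_xml(report, xml_path)
  doc <- read_population_xml(xml_path)
  expect_false(is.null(doc$loci$A$hwe_chisq))
  expect_null(doc$loci$A$hwe_exact)
  expect_length(doc$haplotypes, 0)
  expect_length(doc$ld, 0)
})

test_that("XML write/read round-trips every numeric field at full precision", {
  dir <- withr::local_tempdir()
  report <- run_one_report(dir, permutations = 5)
  xml_path <- file.path(dir, "pop1.xml")
  write_population_xml(report, xml_path)
  doc <- read_population_xml(xml_path)

  af <- report$summary$A$afreq
  expect_identical(doc$loci$A$n_gametes, af$n_gametes)
  expect_identical(doc$loci$A$k, af$k)
  expect_equal(doc$loci$A$alleles$frequency,
               unname(af$freqs[doc$loci$A$alleles$allele]), tolerance = 0)
  expect_equal(doc$loci$A$f_obs, report$summary$A$f_obs, tolerance = 0)
  expect_equal(doc$loci$A$hwe_chisq$pvalue, report$hwe_chisq$A$pvalue, tolerance = 0)
  expect_equal(doc$loci$A$hwe_exact$p_overall, report$hwe_exact$A$p_overall,
               tolerance = 0)
  expect_equal(doc$loci$A$ew$p_value, report$ew$A$p_value, tolerance = 0)
  est <- report$haplotypes[["A:B"]]
  expect_equal(doc$haplotypes[["A:B"]]$loglik, est$loglik, tolerance = 0)
  got <- doc$haplotypes[["A:B"]]$table
  expect_equal(setNames(got$frequency, got$haplotype)[names(sort(-est$freqs))[1]],
               sort(-est$freqs)[1] * -1, tolerance = 0, ignore_attr = TRUE)
  ld <- report$ld[["A:B"]]
  expect_equal(doc$ld[["A:B"]]$wn, ld$wn, tolerance = 0)
  expect_equal(doc$ld[["A:B"]]$ald_1_2, ld$ald_1_2, tolerance = 0)
  expect_equal(doc$ld[["A:B"]]$permutation$p_value, ld$permutation$p_value,
               tolerance = 0)
})

test_that("two populations produce two documents with distinct names", {
  dir <- withr::local_tempdir()
  cfg_path <- make_pipeline_fixture(dir)
  config <- parse_config(cfg_path)
  names_seen <- character(0)
  for (i in 1:2) {
    d <- parse_pop_file(file.path(dir, paste0("pop", i, ".pop")))
    r <- run_population_analysis(d, config, seed = 1)
    p <- file.path(dir, paste0("pop", i, ".xml"))
    write_population_xml(r, p)
    names_seen <- c(names_seen, read_population_xml(p)$name)
  }
  expect_equal(sort(names_seen), c("pop1", "pop2"))
})

test_that("text report shows permutation columns only when a test was run", {
  dir <- withr::local_tempdir()
  r0 <- run_one_report(dir, permutations = 0)
  txt0 <- write_text_report(r0)
  expect_false(any(grepl("# permu", txt0, fixed = TRUE)))
  expect_false(any(grepl("p-value", txt0, fixed = TRUE)))

  dir2 <- withr::local_tempdir()
  r1 <- run_one_report(dir2, permutations = 10)
  txt1 <- write_text_report(r1)
  ld_header <- grep("# permu", txt1, fixed = TRUE, value = TRUE)
  expect_length(ld_header, 1L)
  expect_true(grepl("D'.*Wn.*ALD_1_2.*ALD_2_1.*# permu.*p-value", ld_header))
})

test_that("text report haplotype names use the ~ separator", {
  dir <- withr::local_tempdir()
  r <- run_one_report(dir)
  txt <- write_text_report(r)
  expect_true(any(grepl("01:01~0[78]:0[12]", txt)))
})

test_that("a metadata-only report renders when no analyses are requested", {
  cfg <- parse_config(write_config("[Summary]"))
  spec <- simulation_spec("A", allele_freqs = list(c(x = 0.6, y = 0.4)),
                          n_individuals = 10, seed = 3, name = "bare")
  r <- run_population_analysis(sample_population(spec)$dataset, cfg)
  txt <- write_text_report(r)
  expect_true(any(grepl("Population: bare", txt)))
  expect_false(any(grepl("HardyWeinberg", txt)))
})

test_that("TSV aggregation emits only files whose data exist", {
  dir <- withr::local_tempdir()
  cfg_path <- make_pipeline_fixture(dir)
  config <- parse_config(cfg_path)
  xmls <- character(0)
  for (i in 1:2) {
    d <- parse_pop_file(file.path(dir, paste0("pop", i, ".pop")))
    r <- run_population_analysis(d, config, seed = i)
    p <- file.path(dir, paste0("pop", i, ".xml"))
    write_population_xml(r, p)
    xmls <- c(xmls, p)
  }
  out <- file.path(dir, "tsv")
  written <- aggregate_tsv(xmls, outputdir = out)
  files <- basename(written)
  expect_setequal(files, c("1-locus-summary.tsv", "1-locus-allele.tsv",
                           "1-locus-hardyweinberg.tsv", "2-locus-summary.tsv",
                           "2-locus-haplo.tsv"))
  # dynamically generated: no 3-locus files, no genotype file (not requested)
  expect_false(file.exists(file.path(out, "3-locus-haplo.tsv")))
  expect_false(file.exists(file.path(out, "1-locus-genotype.tsv")))
  # one row per population and locus in the 1-locus summary
  tab <- read.delim(file.path(out, "1-locus-summary.tsv"))
  expect_equal(nrow(tab), 4L)  # 2 populations x 2 loci
  expect_setequal(unique(tab$pop), c("pop1", "pop2"))
  # no permutation run: columns absent
  tab2 <- read.delim(file.path(out, "2-locus-summary.tsv"))
  expect_false(any(c("permu.n", "permu.pvalue") %in% names(tab2)))
  expect_true(all(c("ld.dprime", "ld.wn", "ald.1.2", "ald.2.1") %in% names(tab2)))
})

test_that("TSV schemas match their declared column sets exactly", {
  dir <- withr::local_tempdir()
  cfg_path <- make_pipeline_fixture(dir, permutations = 5,
                                    extra_cfg = c("[Summary]",
                                                  "individualGenotypes = true"))
  config <- parse_config(cfg_path)
  d <- parse_pop_file(file.path(dir, "pop1.pop"))
  r <- run_population_analysis(d, config, seed = 2)
  p <- file.path(dir, "pop1.xml")
  write_population_xml(r, p)
  out <- file.path(dir, "tsv")
  aggregate_tsv(p, outputdir = out)
  cols <- function(f) names(read.delim(file.path(out, f), check.names = FALSE))
  expect_identical(cols("1-locus-summary.tsv"),
                   c("pop", "locus", "n.gametes", "n.typed", "n.untyped", "k",
                     "f.obs", "hw.chisq", "hw.chisq.df", "hw.chisq.pvalue",
                     "ew.e.f", "ew.f.nd", "ew.pvalue"))
  expect_identical(cols("1-locus-allele.tsv"),
                   c("pop", "locus", "allele", "allele.count", "allele.freq"))
  expect_identical(cols("1-locus-genotype.tsv"),
                   c("pop", "locus", "genotype", "genotype.count"))
  expect_identical(cols("1-locus-hardyweinberg.tsv"),
                   c("pop", "locus", "k", "hw.chisq.pvalue", "hw.exact.method",
                     "hw.exact.pvalue", "hw.het.excess.pvalue",
                     "hw.het.deficit.pvalue"))
  expect_identical(cols("2-locus-summary.tsv"),
                   c("pop", "locus1", "locus2", "n.individuals", "loglik",
                     "converged", "ld.dprime", "ld.wn", "ald.1.2", "ald.2.1",
                     "permu.n", "permu.pvalue"))
  expect_identical(cols("2-locus-haplo.tsv"),
                   c("pop", "locus1", "locus2", "haplotype", "haplo.freq",
                     "haplo.count", "ld.d", "ld.dprime"))
})

test_that("IHWG metadata columns appear only when enabled", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec("A", allele_freqs = list(c(x = 0.6, y = 0.4)),
                          n_individuals = 20, seed = 3, name = "popX")
  d <- sample_population(spec)$dataset
  d$metadata <- c(d$metadata, label = "LAB1", region = "Oceania",
                  ethnicity = "example")
  cfg <- parse_config(write_config(c("[HardyWeinberg]")))
  r <- run_population_analysis(d, cfg)
  p <- file.path(dir, "popX.xml")
  write_population_xml(r, p)
  aggregate_tsv(p, outputdir = file.path(dir, "plain"))
  aggregate_tsv(p, outputdir = file.path(dir, "ihwg"), enable_ihwg = TRUE)
  plain <- read.delim(file.path(dir, "plain", "1-locus-summary.tsv"))
  ihwg <- read.delim(file.path(dir, "ihwg", "1-locus-summary.tsv"))
  expect_false(any(c("pop.label", "region", "ethnicity") %in% names(plain)))
  expect_true(all(c("pop.label", "region", "ethnicity") %in% names(ihwg)))
  expect_equal(ihwg$region[1], "Oceania")
})

test_that("n-locus estimation produces the matching n-locus TSV files", {
  dir <- withr::local_tempdir()
  af <- rep(list(c(u = 0.5, v = 0.5)), 5)
  spec <- simulation_spec(paste0("L", 1:5), allele_freqs = af,
                          n_individuals = 25, seed = 12, name = "fiveloc")
  d <- sample_population(spec)$dataset
  cfg <- parse_config(write_config(c(
    "[Haplotypes]", "lociSets = L1:L2:L3:L4:L5")))
  r <- run_population_analysis(d, cfg, seed = 3)
  p <- file.path(dir, "five.xml")
  write_population_xml(r, p)
  out <- file.path(dir, "tsv")
  written <- basename(aggregate_tsv(p, outputdir = out))
  expect_true("5-locus-haplo.tsv" %in% written)
  expect_true("5-locus-summary.tsv" %in% written)
  expect_false("2-locus-haplo.tsv" %in% written)
  expect_false("3-locus-haplo.tsv" %in% written)
})

test_that("aggregation rejects malformed XML and empty input", {
  expect_error(aggregate_tsv(character(0)), "no XML")
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<not-a-report/>", bad)
  expect_error(aggregate_tsv(bad), "malformed XML")
})

test_that("a TSV filename prefix is honored", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec("A", allele_freqs = list(c(x = 0.6, y = 0.4)),
                          n_individuals = 20, seed = 3)
  r <- run_population_analysis(sample_population(spec)$dataset,
                               parse_config(write_config("[HardyWeinberg]")))
  p <- file.path(dir, "x.xml")
  write_population_xml(r, p)
  written <- aggregate_tsv(p, outputdir = dir, prefix = "run1_")
  expect_true(all(startsWith(basename(written), "run1_")))
})
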