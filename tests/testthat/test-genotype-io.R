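# Parsing of .pop genotype files, INI configuration with CustomBinning
# filters, allele binning, and haplotype name formatting.

test_that("a two-locus file with three typed rows parses to n=3, L=2", {
  d <- make_dataset(c("A", "B"),
                    list(c("01:01", "02:01", "07:02", "08:01"),
                         c("01:01", "01:01", "07:02", "07:02"),
                         c("03:01", "02:01", "08:01", "08:01")))
  expect_s3_class(d, "pop_dataset")
  expect_equal(n_individuals(d), 3L)
  expect_equal(d$loci, c("A", "B"))
  expect_equal(d$metadata[["name"]], "test")
})

test_that("the untyped marker makes one individual incomplete at one locus only", {
  d <- make_dataset(c("A", "B"),
                    list(c("01:01", "02:01", "07:02", "08:01"),
                         c("****", "01:01", "07:02", "07:02"),
                         c("03:01", "02:01", "08:01", "08:01")))
  af_a <- count_alleles(d, "A")
  af_b <- count_alleles(d, "B")
  expect_equal(af_a$n_gametes, 4L)      # individual 2 excluded at A
  expect_equal(af_a$n_excluded, 1L)
  expect_equal(af_b$n_gametes, 6L)      # but complete at B
  expect_equal(af_b$n_excluded, 0L)
})

test_that("malformed rows and headers raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".pop")
  writeLines(c("A_1\tA_2\tB_1\tB_2", "x\ty\tz\tw\tv"), f)
  expect_error(parse_pop_file(f), "line 2.*5 allele fields|5 allele fields")

  f2 <- withr::local_tempfile(fileext = ".pop")
  writeLines(c("A_1\tA_2\tB_1", "x\ty\tz"), f2)
  expect_error(parse_pop_file(f2), "two per locus")

  f3 <- withr::local_tempfile(fileext = ".pop")
  writeLines(c("A_1\tA_2\tA_1\tA_2", "x\ty\tz\tw"), f3)
  expect_error(parse_pop_file(f3), "duplicate locus")

  f4 <- withr::local_tempfile(fileext = ".pop")
  writeLines(c("name: x", "A_1\tA_2"), f4)
  expect_error(parse_pop_file(f4), "empty body")
})

test_that("write_pop_file round-trips metadata, loci, genotypes and untyped markers", {
  d <- make_dataset(c("A", "DPB1"),
                    list(c("01:01", "02:01:01:134Q", "1372:01:01:02", "01:01"),
                         c("****", "01:01", "01:01", "****")),
                    metadata = c(name = "rt", region = "here"))
  f <- withr::local_tempfile(fileext = ".pop")
  write_pop_file(d, f)
  d2 <- parse_pop_file(f)
  expect_identical(d2$metadata, d$metadata)
  expect_identical(d2$loci, d$loci)
  expect_identical(d2$allele1, d$allele1)
  expect_identical(d2$allele2, d$allele2)
})

test_that("CRLF input parses identically to LF input", {
  f <- withr::local_tempfile(fileext = ".pop")
  writeLines(c("name: crlf", "A_1\tA_2", "x\ty"), f, sep = "\r\n")
  d <- parse_pop_file(f)
  expect_equal(n_individuals(d), 1L)
  expect_equal(unname(d$allele2[1, 1]), "y")
})

test_that("INI parsing handles ;; comments, sections, and CustomBinning grammar", {
  f <- write_config(c(
    ";; a comment line",
    "[HardyWeinberg]",
    "lumpBelow = 5  ;; trailing comment",
    "[MysterySection]",
    "key = value",
    "[CustomBinning]",
    ";; G-codes",
    "DRB1: !11AD/DRB1*11:01/DRB1*11:04",
    " !13AB/DRB1*13:01/DRB1*13:02",
    "DQB1: !06G/06:01/06:02/06:03"))
  cfg <- parse_config(f)
  expect_equal(config_get(cfg, "HardyWeinberg", "lumpBelow"), "5")
  expect_true("MysterySection" %in% cfg$unknown_sections)
  expect_false("HardyWeinberg" %in% cfg$unknown_sections)
  rules <- cfg$binning$rules
  expect_equal(names(rules), c("DRB1", "DQB1"))
  expect_length(rules$DRB1, 2L)
  expect_equal(rules$DRB1[[1]]$id, "11AD")
  expect_equal(rules$DRB1[[1]]$members, c("DRB1*11:01", "DRB1*11:04"))
  expect_length(rules$DQB1[[1]]$members, 3L)
})

test_that("a config without CustomBinning yields no filter and no error", {
  cfg <- parse_config(write_config(c("[HardyWeinberg]", "lumpBelow = 5")))
  expect_null(cfg$binning)
})

test_that("malformed binning groups are rejected with line numbers", {
  expect_error(parse_config(write_config(c(
    "[CustomBinning]", "DRB1: 11AD/11:01"))), "must begin with '!'")
  expect_error(parse_config(write_config(c(
    "[CustomBinning]", "DRB1: !11AD"))), "at least one member")
  expect_error(parse_config(write_config(c(
    "[CustomBinning]", " !11AD/11:01"))), "no preceding locus")
})

test_that("an allele in two groups of one locus is a conflict error", {
  expect_error(parse_config(write_config(c(
    "[CustomBinning]",
    "DRB1: !g1/11:01/11:04",
    " !g2/11:04/11:05"))), "conflict.*11:04")
})

test_that("a group identifier that is a member elsewhere is a conflict error", {
  expect_error(parse_config(write_config(c(
    "[CustomBinning]",
    "DRB1: !g1/11:01",
    " !g2/g1/11:05"))), "conflict.*g1")
})

test_that("binning replaces members, leaves others untouched, and counts pool", {
  d <- make_dataset("DRB1", list(c("DRB1*11:01", "DRB1*07:01"),
                                 c("DRB1*11:04", "DRB1*11:04")))
  cfg <- parse_config(write_config(c(
    "[CustomBinning]", "DRB1: !11AD/DRB1*11:01/DRB1*11:04")))
  b <- apply_binning(d, cfg$binning)
  af <- count_alleles(b, "DRB1")
  expect_equal(unname(af$counts["11AD"]), 3L)
  expect_equal(unname(af$counts["DRB1*07:01"]), 1L)
  # input untouched
  expect_equal(unname(d$allele1[1, 1]), "DRB1*11:01")
})

test_that("binning with an empty/absent filter is the identity", {
  d <- make_dataset("A", list(c("01:01", "02:01")))
  expect_identical(apply_binning(d, NULL), d)
})

test_that("binning is idempotent and warns on loci absent from the dataset", {
  d <- make_dataset("A", list(c("01:01", "02:01")))
  cfg <- parse_config(write_config(c(
    "[CustomBinning]", "A: !01G/01:01", "ZZ: !x/y")))
  expect_warning(b1 <- apply_binning(d, cfg$binning), "ZZ")
  b2 <- suppressWarnings(apply_binning(b1, cfg$binning))
  expect_identical(b1$allele1, b2$allele1)
  expect_identical(b1$allele2, b2$allele2)
})

test_that("binning matching is case-sensitive", {
  d <- make_dataset("A", list(c("a*01", "A*01")))
  cfg <- parse_config(write_config(c("[CustomBinning]", "A: !G/A*01")))
  b <- apply_binning(d, cfg$binning)
  expect_setequal(unname(c(b$allele1[1, 1], b$allele2[1, 1])), c("a*01", "G"))
})

test_that("untyped alleles pass through binning unchanged", {
  d <- make_dataset("A", list(c("****", "01:01")))
  cfg <- parse_config(write_config(c("[CustomBinning]", "A: !G/01:01")))
  b <- apply_binning(d, cfg$binning)
  expect_true(is.na(b$allele1[1, 1]))
  expect_equal(unname(b$allele2[1, 1]), "G")
})

test_that("haplotype names join with ~ and preserve colons", {
  expect_equal(format_haplotype_name(c("A*01:01", "B*08:01")), "A*01:01~B*08:01")
  expect_equal(format_haplotype_name("01:01"), "01:01")
  nm <- format_haplotype_name(paste0("L", 1:5))
  expect_equal(lengths(regmatches(nm, gregexpr("~", nm))), 4L)
  expect_error(format_haplotype_name(c("01:01", NA)), "untyped")
})
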