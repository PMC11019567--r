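# Fixture builders shared across the suite. All data is generated in code.

# Build a pop_dataset by writing the .pop dialect to a temp file and parsing
# it, so fixtures also exercise the parser.
make_dataset <- function(loci, rows, metadata = c(name = "test"),
                         untyped = "****") {
  lines <- character(0)
  if (length(metadata) > 0) {
    lines <- c(lines, paste0(names(metadata), ": ", metadata))
  }
  header <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  lines <- c(lines, paste(header, collapse = "\t"))
  lines <- c(lines, vapply(rows, paste, "", collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".pop", .local_envir = parent.frame())
  writeLines(lines, f)
  parse_pop_file(f, untyped_marker = untyped)
}

# Single-locus dataset from a vector of "a/b" genotype strings.
single_locus_dataset <- function(genos, locus = "L") {
  rows <- lapply(strsplit(genos, "/", fixed = TRUE), identity)
  make_dataset(locus, rows)
}

write_config <- function(lines, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".ini", .local_envir = envir)
  writeLines(lines, f)
  f
}

# Random I x J haplotype frequency table (strictly positive margins).
random_h <- function(I, J) {
  repeat {
    x <- matrix(stats::rexp(I * J), I, J)
    h <- x / sum(x)
    if (min(rowSums(h)) > 1e-3 && min(colSums(h)) > 1e-3) {
      dimnames(h) <- list(paste0("a", seq_len(I)), paste0("b", seq_len(J)))
      return(h)
    }
  }
}

# Independent brute-force evaluation of the ALD homozygosity formulas,
# written with explicit loops so it shares nothing with the implementation.
ald_brute <- function(h) {
  p <- rowSums(h); q <- colSums(h)
  F1 <- 0
  for (i in seq_along(p)) F1 <- F1 + p[i]^2
  F2 <- 0
  for (j in seq_along(q)) F2 <- F2 + q[j]^2
  F1g2 <- 0
  for (j in seq_along(q)) {
    if (q[j] > 0) for (i in seq_along(p)) F1g2 <- F1g2 + h[i, j]^2 / q[j]
  }
  F2g1 <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) for (j in seq_along(q)) F2g1 <- F2g1 + h[i, j]^2 / p[i]
  }
  w12 <- if (F1 < 1) sqrt(max(0, (F1g2 - F1) / (1 - F1))) else NA_real_
  w21 <- if (F2 < 1) sqrt(max(0, (F2g1 - F2) / (1 - F2))) else NA_real_
  c(w12 = w12, w21 = w21)
}

# The worked 2x3 haplotype table used throughout the LD tests.
h_2x3 <- function() {
  matrix(c(0.4, 0.0, 0.1, 0.2, 0.0, 0.3), 2, 3,
         dimnames = list(c("a1", "a2"), c("b1", "b2", "b3")))
}

# Standard analysis configuration for pipeline tests.
standard_config_lines <- function(permutations = 0, loci_sets = "A:B",
                                  extra = character(0)) {
  c(";; pipeline test configuration",
    "[HardyWeinberg]", "lumpBelow = 5",
    "[HardyWeinbergExact]", "numSamples = 300",
    "[EwensWatterson]", "numSamples = 300",
    "[Haplotypes]", paste("lociSets =", loci_sets),
    "[LinkageDisequilibrium]", "pairs = all",
    paste("permutations =", permutations),
    extra)
}
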