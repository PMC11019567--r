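# Reading and validating population genotype files, INI configuration and
# custom allele-binning filters.
#
# The .pop dialect accepted here:
#   * optional leading metadata lines of the form "key: value" (no tabs);
#   * a tab-separated header row with two columns per locus, named
#     "<locus>_1" and "<locus>_2";
#   * one tab-separated data row per individual, two allele fields per locus;
#   * untyped alleles carry the untyped marker (default "****").
# Both LF and CRLF line endings are accepted; encoding is UTF-8.

DEFAULT_UNTYPED_MARKER <- "****"

new_pop_dataset <- function(metadata, loci, allele1, allele2,
                            untyped_marker = DEFAULT_UNTYPED_MARKER) {
  stopifnot(is.matrix(allele1), is.matrix(allele2),
            ncol(allele1) == length(loci), ncol(allele2) == length(loci))
  colnames(allele1) <- loci
  colnames(allele2) <- loci
  structure(
    list(metadata = metadata, loci = loci,
         allele1 = allele1, allele2 = allele2,
         untyped_marker = untyped_marker),
    class = "pop_dataset"
  )
}

#' Number of individuals in a population dataset
#'
#' @param dataset A `pop_dataset`.
#' @return Integer count of individuals (rows).
#' @export
n_individuals <- function(dataset) {
  stopifnot(inherits(dataset, "pop_dataset"))
  nrow(dataset$allele1)
}

#' @export
print.pop_dataset <- function(x, ...) {
  cat("Population dataset:", x$metadata["name"] %||% "<unnamed>", "\n")
  cat("  individuals:", n_individuals(x), "\n")
  cat("  loci (", length(x$loci), "): ", paste(x$loci, collapse = ", "), "\n",
      sep = "")
  n_untyped <- sum(is.na(x$allele1)) + sum(is.na(x$allele2))
  cat("  untyped allele fields:", n_untyped, "\n")
  invisible(x)
}

#' Parse a plaintext population genotype (.pop) file
#'
#' Reads a tab-separated genotype file with optional `key: value` metadata
#' lines, a header naming two columns per locus (`<locus>_1`, `<locus>_2`)
#' and one row per individual. Fields equal to the untyped marker become
#' untyped alleles (stored as `NA`); an individual with any untyped member
#' at a locus is incomplete at that locus and is excluded from that locus's
#' single-locus statistics.
#'
#' @param file Path to the file (or a connection).
#' @param untyped_marker Token marking an untyped allele; default `"****"`.
#' @return A `pop_dataset` with elements `metadata` (named character),
#'   `loci`, and per-individual allele matrices.
#' @examples
#' f <- tempfile(fileext = ".pop")
#' writeLines(c("name: demo", "A_1\tA_2", "01:01\t02:01"), f)
#' d <- parse_pop_file(f)
#' n_individuals(d)
#' @export
parse_pop_file <- function(file, untyped_marker = DEFAULT_UNTYPED_MARKER) {
  lines <- read_text_lines(file)
  # metadata: leading non-tab "key: value" lines
  metadata <- character(0)
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines && !grepl("\t", lines[i], fixed = TRUE)) {
    ln <- lines[i]
    if (!grepl("^\\s*$", ln)) {
      m <- regexec("^([^:\t]+):\\s*(.*)$", ln)
      parts <- regmatches(ln, m)[[1]]
      if (length(parts) != 3L) {
        stop(sprintf("line %d: expected 'key: value' metadata before the header", i),
             call. = FALSE)
      }
      metadata[trimws(parts[2])] <- trimws(parts[3])
    }
    i <- i + 1L
  }
  if (i > n_lines) stop("no tab-separated header row found", call. = FALSE)

  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) %% 2L != 0L) {
    stop(sprintf("line %d: header has %d allele columns; two per locus required",
                 i, length(header)), call. = FALSE)
  }
  n_loci <- length(header) %/% 2L
  loci <- character(n_loci)
  for (j in seq_len(n_loci)) {
    c1 <- header[2L * j - 1L]
    c2 <- header[2L * j]
    if (!grepl("_1$", c1) || !grepl("_2$", c2) ||
        sub("_1$", "", c1) != sub("_2$", "", c2)) {
      stop(sprintf("line %d: header columns '%s'/'%s' are not a <locus>_1/<locus>_2 pair",
                   i, c1, c2), call. = FALSE)
    }
    loci[j] <- sub("_1$", "", c1)
  }
  if (anyDuplicated(loci)) {
    stop(sprintf("duplicate locus name '%s' in header", loci[anyDuplicated(loci)]),
         call. = FALSE)
  }

  body_idx <- seq.int(i + 1L, length.out = max(0L, n_lines - i))
  body_idx <- body_idx[!grepl("^\\s*$", lines[body_idx])]
  if (length(body_idx) == 0L) stop("empty body: no individuals", call. = FALSE)

  a1 <- matrix(NA_character_, nrow = length(body_idx), ncol = n_loci)
  a2 <- matrix(NA_character_, nrow = length(body_idx), ncol = n_loci)
  for (r in seq_along(body_idx)) {
    fields <- strsplit(lines[body_idx[r]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 2L * n_loci) {
      stop(sprintf("line %d: row has %d allele fields, expected %d",
                   body_idx[r], length(fields), 2L * n_loci), call. = FALSE)
    }
    if (any(fields == "")) {
      stop(sprintf("line %d: empty allele field", body_idx[r]), call. = FALSE)
    }
    odd <- fields[seq(1L, length(fields), by = 2L)]
    even <- fields[seq(2L, length(fields), by = 2L)]
    a1[r, ] <- ifelse(odd == untyped_marker, NA_character_, odd)
    a2[r, ] <- ifelse(even == untyped_marker, NA_character_, even)
  }
  new_pop_dataset(metadata, loci, a1, a2, untyped_marker)
}

#' Write a population dataset as a .pop file
#'
#' Inverse of [parse_pop_file()]: a written file parses back to an identical
#' dataset (metadata, loci, genotypes and untyped positions).
#'
#' @param dataset A `pop_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pop_file <- function(dataset, path) {
  stopifnot(inherits(dataset, "pop_dataset"))
  if (n_individuals(dataset) == 0L) {
    stop("refusing to write a dataset with 0 individuals", call. = FALSE)
  }
  out <- character(0)
  if (length(dataset$metadata) > 0L) {
    out <- c(out, paste0(names(dataset$metadata), ": ", dataset$metadata))
  }
  header <- as.vector(rbind(paste0(dataset$loci, "_1"), paste0(dataset$loci, "_2")))
  out <- c(out, paste(header, collapse = "\t"))
  mk <- dataset$untyped_marker
  a1 <- dataset$allele1
  a2 <- dataset$allele2
  a1[is.na(a1)] <- mk
  a2[is.na(a2)] <- mk
  n_loci <- length(dataset$loci)
  for (r in seq_len(nrow(a1))) {
    fields <- character(2L * n_loci)
    fields[seq(1L, 2L * n_loci, by = 2L)] <- a1[r, ]
    fields[seq(2L, 2L * n_loci, by = 2L)] <- a2[r, ]
    out <- c(out, paste(fields, collapse = "\t"))
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# INI configuration and CustomBinning filters

KNOWN_SECTIONS <- c("Summary", "HardyWeinberg", "HardyWeinbergExact",
                    "EwensWatterson", "Haplotypes", "LinkageDisequilibrium",
                    "CustomBinning", "Simulation")

#' Parse an INI analysis-configuration file
#'
#' Parses INI syntax (`[Section]` headers, `key = value` pairs) with
#' double-semicolon (`;;`) comments. A `[CustomBinning]` section, if present,
#' is parsed into a binning filter: each locus introduces groups on lines of
#' the form `locus: !identifier/member/member/...`, with additional groups
#' for the same locus on continuation lines that begin with whitespace and
#' an exclamation point. When the filter is applied, member alleles are
#' converted to the group identifier.
#'
#' @param file Path to the .ini file (or a connection).
#' @return An `analysis_config`: a list with `sections` (named list of named
#'   character vectors), `unknown_sections` (sections preserved but not
#'   recognized by any analysis module) and `binning` (a `binning_filter`
#'   or `NULL`).
#' @export
parse_config <- function(file) {
  raw <- read_text_lines(file)
  # strip ;; comments (to end of line), keep leading whitespace intact
  lines <- sub(";;.*$", "", raw)

  sections <- list()
  binning_rules <- list()
  current <- NULL
  current_locus <- NULL

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln)) next
    if (grepl("^\\[.*\\]\\s*$", trimws(ln))) {
      current <- sub("^\\[(.*)\\]$", "\\1", trimws(ln))
      current_locus <- NULL
      if (current != "CustomBinning" && is.null(sections[[current]])) {
        sections[[current]] <- character(0)
      }
      next
    }
    if (is.null(current)) {
      stop(sprintf("line %d: content before any [section] header", i), call. = FALSE)
    }
    if (current == "CustomBinning") {
      is_continuation <- grepl("^\\s", ln)
      body <- trimws(ln)
      if (is_continuation) {
        if (is.null(current_locus)) {
          stop(sprintf("line %d: continuation line with no preceding locus", i),
               call. = FALSE)
        }
        if (!startsWith(body, "!")) {
          stop(sprintf("line %d: binning continuation line must begin with '!'", i),
               call. = FALSE)
        }
        grp <- parse_binning_group(body, i)
        binning_rules[[current_locus]] <- c(binning_rules[[current_locus]], list(grp))
      } else {
        m <- regexec("^([^:!]+):\\s*(.*)$", body)
        parts <- regmatches(body, m)[[1]]
        if (length(parts) != 3L) {
          stop(sprintf("line %d: expected 'locus: !group/...' in [CustomBinning]", i),
               call. = FALSE)
        }
        current_locus <- trimws(parts[2])
        rest <- trimws(parts[3])
        if (!startsWith(rest, "!")) {
          stop(sprintf("line %d: first group line for locus '%s' must begin with '!'",
                       i, current_locus), call. = FALSE)
        }
        grp <- parse_binning_group(rest, i)
        binning_rules[[current_locus]] <- c(binning_rules[[current_locus]], list(grp))
      }
    } else {
      m <- regexec("^\\s*([^=:]+?)\\s*[=:]\\s*(.*)$", ln)
      parts <- regmatches(ln, m)[[1]]
      if (length(parts) != 3L) {
        stop(sprintf("line %d: expected 'key = value'", i), call. = FALSE)
      }
      sections[[current]][trimws(parts[2])] <- trimws(parts[3])
    }
  }

  binning <- if (length(binning_rules) > 0L) new_binning_filter(binning_rules) else NULL
  unknown <- setdiff(names(sections), KNOWN_SECTIONS)
  structure(
    list(sections = sections, unknown_sections = unknown, binning = binning),
    class = "analysis_config"
  )
}

parse_binning_group <- function(body, line_no) {
  fields <- strsplit(sub("^!", "", body), "/", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  fields <- fields[fields != ""]
  if (length(fields) < 2L) {
    stop(sprintf("line %d: binning group needs an identifier and at least one member",
                 line_no), call. = FALSE)
  }
  list(id = fields[1], members = fields[-1])
}

new_binning_filter <- function(rules) {
  # conflict checks: within one locus no allele may belong to two groups, and
  # a group identifier may not itself be a member of another group (binning
  # is deliberately non-transitive).
  for (locus in names(rules)) {
    members <- unlist(lapply(rules[[locus]], `[[`, "members"))
    if (anyDuplicated(members)) {
      dup <- members[duplicated(members)][1]
      stop(sprintf("binning conflict at locus %s: allele '%s' appears in two groups",
                   locus, dup), call. = FALSE)
    }
    ids <- vapply(rules[[locus]], `[[`, "", "id")
    clash <- intersect(ids, members)
    if (length(clash) > 0L) {
      stop(sprintf("binning conflict at locus %s: group identifier '%s' is also a member of another group",
                   locus, clash[1]), call. = FALSE)
    }
  }
  structure(list(rules = rules), class = "binning_filter")
}

#' Get a configuration value with a default
#'
#' @param config An `analysis_config`.
#' @param section,key Section and key names.
#' @param default Value returned when the key is absent.
#' @return The value as character, or `default`.
#' @export
config_get <- function(config, section, key, default = NULL) {
  v <- config$sections[[section]][key]
  if (is.null(v) || is.na(v)) default else unname(v)
}

#' Apply a custom allele-binning filter to a dataset
#'
#' Replaces every allele that is a member of a binning group by the group
#' identifier, at the group's locus. Alleles not mentioned in any group, and
#' untyped alleles, pass through unchanged. The input dataset is not
#' modified. Filter loci absent from the dataset are ignored with a warning.
#'
#' @param dataset A `pop_dataset`.
#' @param filter A `binning_filter` (from [parse_config()]), or `NULL` for a
#'   no-op.
#' @return A new `pop_dataset` with binned allele names.
#' @export
apply_binning <- function(dataset, filter) {
  stopifnot(inherits(dataset, "pop_dataset"))
  if (is.null(filter)) return(dataset)
  stopifnot(inherits(filter, "binning_filter"))
  extra <- setdiff(names(filter$rules), dataset$loci)
  if (length(extra) > 0L) {
    warning("binning filter loci not in dataset (ignored): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- dataset
  for (locus in intersect(names(filter$rules), dataset$loci)) {
    map <- character(0)
    for (grp in filter$rules[[locus]]) {
      map[grp$members] <- grp$id
    }
    j <- match(locus, dataset$loci)
    for (slot in c("allele1", "allele2")) {
      col <- out[[slot]][, j]
      hit <- !is.na(col) & col %in% names(map)
      col[hit] <- map[col[hit]]
      out[[slot]][, j] <- col
    }
  }
  out
}

#' Format a multi-locus haplotype name
#'
#' Joins allele names with the GL String `~` separator, in locus order.
#' Colon-delimited HLA-style allele names are preserved verbatim.
#'
#' @param alleles Character vector of allele names, one per locus.
#' @return A single haplotype name string, e.g. `"A*01:01~B*08:01"`.
#' @examples
#' format_haplotype_name(c("A*01:01", "B*08:01"))
#' @export
format_haplotype_name <- function(alleles) {
  if (length(alleles) == 0L) stop("empty allele list", call. = FALSE)
  if (anyNA(alleles) || any(alleles == "")) {
    stop("cannot format a haplotype containing untyped alleles", call. = FALSE)
  }
  paste(alleles, collapse = "~")
}
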