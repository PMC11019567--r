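# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
read_text_lines <- function(file) {
  if (inherits(file, "connection")) {
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  }
  # accept CRLF input
  sub("\r$", "", lines)
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so analysis seeds never leak into user code. A NULL seed
# leaves the RNG stream alone.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a master seed, kept inside 32-bit
# integer range.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483587)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-precision numeric formatting for machine-readable output; survives a
# write/read round trip at double precision.
#' @keywords internal
#' @noRd
fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' @keywords internal
#' @noRd
fmt_sig6 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

#' @keywords internal
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
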