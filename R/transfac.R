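#' Position weight matrix objects
#'
#' A `pwm` is a parsed TRANSFAC-style count matrix together with the derived
#' quantities used by the scanner: row-normalised base frequencies, the
#' per-position information vector and the location of the 5-position
#' high-information core.
#'
#' @param counts numeric L x 4 matrix of base counts, columns A, C, G, T.
#' @param matrix_id accession string (e.g. `"M00001"`).
#' @param factor_name factor identifier (e.g. `"V$ISRE_01"`).
#' @return An object of class `pwm`: a list with elements `matrix_id`,
#'   `factor_name`, `counts`, `frequencies`, `info`, `core_start` (1-based
#'   index of the first core position), `core_len`, and `core_whole`
#'   (`TRUE` when the matrix is shorter than 5 positions and the core is the
#'   whole matrix).
#' @examples
#' m <- pwm(matrix(c(10, 0, 0, 0,
#'                   5, 5, 0, 0,
#'                   0, 0, 0, 10), ncol = 4, byrow = TRUE), "M1", "V$TOY")
#' m$frequencies
#' @export
pwm <- function(counts, matrix_id = "PWM", factor_name = matrix_id) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("a PWM needs exactly 4 count columns (A, C, G, T)")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("PWM counts must be finite and non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("PWM '", matrix_id, "' has a zero count row (position ",
         paste(which(rs == 0), collapse = ", "), ")")
  colnames(counts) <- DNA_BASES
  freq <- counts / rs
  info <- apply(freq, 1L, .row_information)
  obj <- list(
    matrix_id   = matrix_id,
    factor_name = factor_name,
    counts      = counts,
    frequencies = freq,
    info        = info
  )
  core <- .find_core(info)
  obj$core_start <- core$start
  obj$core_len   <- core$len
  obj$core_whole <- core$whole
  class(obj) <- "pwm"
  obj
}

DNA_BASES <- c("A", "C", "G", "T")

## f * ln(4 f) summed over bases, with 0 * ln 0 := 0
.row_information <- function(f) {
  nz <- f > 0
  sum(f[nz] * log(4 * f[nz]))
}

## 5-position window of maximal summed information, leftmost on ties;
## matrices shorter than 5 use the whole matrix as core (flagged)
.find_core <- function(info) {
  L <- length(info)
  if (L < 5L)
    return(list(start = 1L, len = L, whole = TRUE))
  s <- vapply(seq_len(L - 4L), function(i) sum(info[i:(i + 4L)]), 0)
  list(start = which.max(s), len = 5L, whole = FALSE)
}

#' Per-position information vector of a PWM
#'
#' For each matrix position the information weight is
#' \eqn{\sum_b f_b \ln(4 f_b)} (natural log, `0 ln 0 := 0`): zero for a
#' uniform position, `ln 4` for a fully determined one. These weights
#' emphasise well-conserved positions in the matrix similarity score.
#'
#' @param x a [pwm] object.
#' @return numeric vector of length `L`, all entries in `[0, ln 4]`.
#' @export
information_vector <- function(x) {
  stopifnot(inherits(x, "pwm"))
  x$info
}

#' Core of a PWM
#'
#' The core is the run of 5 consecutive positions with maximal summed
#' information (leftmost on ties). Matrices shorter than 5 positions use the
#' whole matrix as core and are flagged.
#'
#' @param x a [pwm] object.
#' @return list with `start` (1-based first core position), `len`, and
#'   `whole` (`TRUE` if the core is the entire matrix).
#' @export
core_of <- function(x) {
  stopifnot(inherits(x, "pwm"))
  list(start = x$core_start, len = x$core_len, whole = x$core_whole)
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$matrix_id, "(", x$factor_name, ")\n")
  cat("  length:", nrow(x$counts), " core:", x$core_start, "..",
      x$core_start + x$core_len - 1L,
      if (x$core_whole) "(whole matrix)" else "", "\n")
  cat("  consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Consensus string of a PWM (argmax base per position, leftmost on ties)
#' @param x a [pwm] object.
#' @return character string of length `L`.
#' @export
consensus_string <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$frequencies, 1L, which.max)], collapse = "")
}

#' Parse TRANSFAC-format matrix records
#'
#' Reads the TRANSFAC flat-file matrix format: records delimited by `//`,
#' each with `AC` (accession) and `ID` (factor) lines, a `P0` column header
#' and numbered count rows `NN  a  c  g  t  [consensus]`. The column order
#' given on the `P0` line is honoured.
#'
#' @param file path to a TRANSFAC matrix file, or `NULL` when `text` given.
#' @param text character vector of lines (alternative to `file`).
#' @return list of [pwm] objects, named by accession. Empty input gives an
#'   empty list. Records whose count rows sum to zero at any position are
#'   rejected with a warning; malformed rows (wrong column count, negative
#'   or non-numeric counts) are an error naming the record and line.
#' @export
parse_transfac <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be given")
    text <- readLines(file, warn = FALSE)
  } else if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text <- trimws(text, which = "right")
  if (!length(text) || all(!nzchar(text))) return(list())

  out <- list()
  ac <- id <- NA_character_
  order <- DNA_BASES
  rows <- list()
  lineno <- 0L
  flush_record <- function() {
    if (is.na(ac) && is.na(id) && !length(rows)) return(invisible())
    rec <- if (!is.na(ac)) ac else id
    if (!length(rows))
      stop("TRANSFAC record '", rec, "' has no count rows")
    counts <- do.call(rbind, rows)
    ## reorder columns into A,C,G,T regardless of P0 order
    counts <- counts[, match(DNA_BASES, order), drop = FALSE]
    if (any(rowSums(counts) == 0)) {
      warning("rejecting TRANSFAC record '", rec,
              "': zero count row", call. = FALSE)
      return(invisible())
    }
    p <- pwm(counts, matrix_id = rec,
             factor_name = if (!is.na(id)) id else rec)
    out[[rec]] <<- p
    invisible()
  }
  reset <- function() {
    ac <<- NA_character_; id <<- NA_character_
    order <<- DNA_BASES; rows <<- list()
  }

  for (ln in text) {
    lineno <- lineno + 1L
    if (!nzchar(ln)) next
    tag <- substr(ln, 1L, 2L)
    if (tag == "//") { flush_record(); reset(); next }
    if (tag == "AC") { ac <- trimws(sub("^AC\\s*", "", ln)); next }
    if (tag == "ID") { id <- trimws(sub("^ID\\s*", "", ln)); next }
    if (tag == "P0" || tag == "PO") {
      flds <- strsplit(trimws(ln), "\\s+")[[1L]][-1L]
      if (!setequal(toupper(flds), DNA_BASES))
        stop("bad P0 header at line ", lineno, ": ", ln)
      order <- toupper(flds)
      next
    }
    if (grepl("^[0-9]+\\s", ln)) {
      flds <- strsplit(trimws(ln), "\\s+")[[1L]][-1L]
      ## trailing consensus letter(s) are non-numeric and dropped
      num <- suppressWarnings(as.numeric(flds))
      vals <- num[!is.na(num)]
      if (any(is.na(num)) && !all(which(is.na(num)) > length(vals)))
        stop("malformed count row in record '",
             if (!is.na(ac)) ac else id, "' at line ", lineno, ": ", ln)
      if (length(vals) != 4L || any(vals < 0))
        stop("malformed count row in record '",
             if (!is.na(ac)) ac else id, "' at line ", lineno,
             ": expected 4 non-negative counts")
      rows[[length(rows) + 1L]] <- vals
      next
    }
    ## other tags (DE, BF, XX, ...) are ignored
  }
  flush_record()
  out
}

#' Write PWMs in TRANSFAC flat-file format
#'
#' @param pwms list of [pwm] objects.
#' @param file output path.
#' @export
write_transfac <- function(pwms, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(
      paste("AC ", p$matrix_id),
      "XX",
      paste("ID ", p$factor_name),
      "XX",
      "P0      A      C      G      T"
    ), con)
    for (i in seq_len(nrow(p$counts))) {
      writeLines(sprintf("%02d %6g %6g %6g %6g  %s",
                         i, p$counts[i, 1L], p$counts[i, 2L],
                         p$counts[i, 3L], p$counts[i, 4L],
                         DNA_BASES[which.max(p$frequencies[i, ])]), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(file)
}
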