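## Sequence encoding and the matrix-similarity scanner.
##
## Sequences are encoded as integer vectors (A=1, C=2, G=3, T=4, anything
## else NA) so that per-position score lookups are plain vector indexing.

.ENC <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v
})

.encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .ENC[utf8ToInt(x)]
}

## reverse complement of an encoded vector; NA stays NA
.revcomp_enc <- function(s) rev(5L - s)

#' Reverse complement of a DNA string
#'
#' Keeps `N` (and any non-ACGT character) as `N`. Case is not preserved.
#'
#' @param x single character string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  s <- .revcomp_enc(.encode_seq(x))
  out <- rep("N", length(s))
  out[!is.na(s)] <- DNA_BASES[s[!is.na(s)]]
  paste(out, collapse = "")
}

## Per-PWM scoring tables: weight matrix W (4 x L) with W[b, i] =
## info[i] * f(i, b), plus per-position min/max contributions.
.score_tables <- function(p) {
  W <- t(p$frequencies * p$info)           # 4 x L
  list(
    W    = W,
    minv = apply(W, 2L, min),
    maxv = apply(W, 2L, max)
  )
}

#' Matrix similarity score of a window
#'
#' The information-weighted, min-max normalised match score in `[0, 1]`:
#' \deqn{\mathrm{MSS} = \frac{\mathrm{Current} - \mathrm{Min}}
#'                           {\mathrm{Max} - \mathrm{Min}}}
#' with \eqn{\mathrm{Current} = \sum_i I(i) f(i, w_i)} and Min/Max the
#' per-position minimal/maximal attainable contributions. A window
#' containing any non-ACGT character scores 0; a zero-information matrix
#' (Max = Min) scores 1 on every window.
#'
#' @param x a [pwm] object.
#' @param window character string of length `L`, or encoded integer vector.
#' @return numeric score in `[0, 1]`.
#' @export
mss_score <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  s <- if (is.character(window)) .encode_seq(window) else as.integer(window)
  L <- nrow(x$counts)
  if (length(s) != L)
    stop("window length ", length(s), " != matrix length ", L)
  tb <- .score_tables(x)
  .mss_at(tb, s, seq_len(L))
}

## MSS restricted to matrix positions `pos` of window `s` (full-length
## encoded window); returns 0 for windows with N at a used position
.mss_at <- function(tb, s, pos) {
  b <- s[pos]
  if (anyNA(b)) return(0)
  cur <- sum(tb$W[cbind(b, pos)])
  lo <- sum(tb$minv[pos]); hi <- sum(tb$maxv[pos])
  if (hi == lo) return(1)
  (cur - lo) / (hi - lo)
}

#' Core score of a window
#'
#' The MSS restricted to the 5 consecutive highest-information positions of
#' the matrix (the whole matrix when shorter than 5 positions).
#'
#' @inheritParams mss_score
#' @return numeric score in `[0, 1]`.
#' @export
core_score <- function(x, window) {
  stopifnot(inherits(x, "pwm"))
  s <- if (is.character(window)) .encode_seq(window) else as.integer(window)
  L <- nrow(x$counts)
  if (length(s) != L)
    stop("window length ", length(s), " != matrix length ", L)
  tb <- .score_tables(x)
  .mss_at(tb, s, x$core_start:(x$core_start + x$core_len - 1L))
}

#' Scan thresholds
#'
#' @param min_mss minimum matrix similarity score (default 0.85).
#' @param min_core minimum core score (default 0.99).
#' @return list with elements `min_mss`, `min_core`.
#' @export
scan_thresholds <- function(min_mss = 0.85, min_core = 0.99) {
  stopifnot(min_mss >= 0, min_mss <= 1, min_core >= 0, min_core <= 1)
  list(min_mss = min_mss, min_core = min_core)
}

## Vectorised one-strand scan of an encoded sequence. Returns positions
## (1-based window starts in `s`), mss and core scores of windows passing
## both thresholds. Core scores are evaluated first; the full MSS only at
## core-passing offsets (identical result, fewer evaluations).
.scan_one_strand <- function(tb, core_pos, L, s, th) {
  n <- length(s)
  nw <- n - L + 1L
  if (nw < 1L) return(NULL)
  ## core score for every offset; the lo/hi bounds are accumulated in the
  ## same stepwise order as the window scores so that a consensus window
  ## scores exactly 1 (and an anti-consensus window exactly 0)
  cur <- numeric(nw)
  na <- logical(nw)
  lo <- hi <- 0
  for (i in core_pos) {
    b <- s[i:(i + nw - 1L)]
    w <- tb$W[, i][b]
    na <- na | is.na(w)
    w[is.na(w)] <- 0
    cur <- cur + w
    lo <- lo + tb$minv[i]
    hi <- hi + tb$maxv[i]
  }
  cs <- if (hi == lo) rep(1, nw) else
    pmin(pmax((cur - lo) / (hi - lo), 0), 1)
  cs[na] <- 0
  cand <- which(cs >= th$min_core)
  if (!length(cand)) return(NULL)
  ## full MSS at the candidates
  cur <- numeric(length(cand))
  na <- logical(length(cand))
  lo <- hi <- 0
  for (i in seq_len(L)) {
    b <- s[cand + i - 1L]
    w <- tb$W[, i][b]
    na <- na | is.na(w)
    w[is.na(w)] <- 0
    cur <- cur + w
    lo <- lo + tb$minv[i]
    hi <- hi + tb$maxv[i]
  }
  ms <- if (hi == lo) rep(1, length(cand)) else
    pmin(pmax((cur - lo) / (hi - lo), 0), 1)
  ms[na] <- 0
  keep <- ms >= th$min_mss
  if (!any(keep)) return(NULL)
  data.frame(pos = cand[keep], mss = ms[keep], core_score = cs[cand][keep])
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window (offset x strand) whose core score meets `min_core` and
#' whose full MSS meets `min_mss` is reported. Minus-strand hits are
#' matches of the matrix to the reverse complement, reported at the
#' window's start offset in the sequence's own (gene) orientation. Windows
#' containing non-ACGT characters never match.
#'
#' @param x a [pwm] object.
#' @param sequence character string (gene orientation).
#' @param thresholds a [scan_thresholds] list.
#' @param start_rel TSS-relative coordinate of the first sequence base
#'   (default 0); reported offsets are `start_rel + position - 1`.
#' @param promoter_id identifier copied into the hit table.
#' @return data.frame with columns `promoter_id`, `matrix_id`, `offset`,
#'   `strand`, `mss`, `core_score`, sorted by offset then strand
#'   (`+` before `-`). Zero rows when nothing matches.
#' @export
scan_sequence <- function(x, sequence, thresholds = scan_thresholds(),
                          start_rel = 0L, promoter_id = "seq") {
  stopifnot(inherits(x, "pwm"))
  s <- if (is.character(sequence)) .encode_seq(sequence)
       else as.integer(sequence)
  L <- nrow(x$counts)
  tb <- .score_tables(x)
  core_pos <- x$core_start:(x$core_start + x$core_len - 1L)
  n <- length(s)

  fwd <- .scan_one_strand(tb, core_pos, L, s, thresholds)
  rev <- .scan_one_strand(tb, core_pos, L, .revcomp_enc(s), thresholds)

  hits <- list()
  if (!is.null(fwd))
    hits$f <- data.frame(offset = start_rel + fwd$pos - 1L, strand = "+",
                         mss = fwd$mss, core_score = fwd$core_score)
  if (!is.null(rev)) {
    ## window at position q of the reverse complement covers original
    ## positions (n - q - L + 2) .. (n - q + 1)
    p <- n - rev$pos - L + 2L
    hits$r <- data.frame(offset = start_rel + p - 1L, strand = "-",
                         mss = rev$mss, core_score = rev$core_score)
  }
  if (!length(hits))
    return(data.frame(promoter_id = character(), matrix_id = character(),
                      offset = integer(), strand = character(),
                      mss = numeric(), core_score = numeric()))
  h <- do.call(rbind, hits)
  h <- h[order(h$offset, h$strand), , drop = FALSE]
  data.frame(promoter_id = promoter_id, matrix_id = x$matrix_id, h,
             row.names = NULL)
}

#' Scan a promoter set with a collection of PWMs
#'
#' @param pwms a [pwm] object or list of them.
#' @param promoters a promoter table from [extract_promoters()].
#' @param thresholds a [scan_thresholds] list.
#' @return combined hit data.frame (see [scan_sequence()]).
#' @export
scan_promoters <- function(pwms, promoters, thresholds = scan_thresholds()) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  enc <- lapply(promoters$sequence, .encode_seq)
  out <- vector("list", length(pwms) * nrow(promoters))
  k <- 0L
  for (p in pwms) {
    for (i in seq_len(nrow(promoters))) {
      k <- k + 1L
      out[[k]] <- scan_sequence(p, enc[[i]], thresholds,
                                start_rel = promoters$start_rel[i],
                                promoter_id = promoters$gene_id[i])
    }
  }
  out <- out[vapply(out, nrow, 0L) > 0L]
  if (!length(out))
    return(data.frame(promoter_id = character(), matrix_id = character(),
                      offset = integer(), strand = character(),
                      mss = numeric(), core_score = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Base counts of matched windows for a-posteriori logo construction
#'
#' Collects the actual sequence content under every hit of one matrix:
#' minus-strand windows are reverse-complemented first, so all windows are
#' in matrix orientation. The resulting L x 4 count matrix is suitable for
#' rendering an information-content logo of what was really matched.
#'
#' @param hits hit table (one `matrix_id` only).
#' @param promoters promoter table providing the sequences the hits refer to.
#' @param x the [pwm] the hits were produced with (supplies the length).
#' @return integer L x 4 matrix, columns A, C, G, T. A zero matrix (with a
#'   warning) when `hits` is empty.
#' @export
logo_counts <- function(hits, promoters, x) {
  stopifnot(inherits(x, "pwm"))
  L <- nrow(x$counts)
  counts <- matrix(0L, L, 4L, dimnames = list(NULL, DNA_BASES))
  if (!nrow(hits)) {
    warning("no hits: returning a zero logo count matrix")
    return(counts)
  }
  if (length(unique(hits$matrix_id)) > 1L)
    stop("logo_counts expects hits from a single matrix")
  idx <- match(hits$promoter_id, promoters$gene_id)
  if (anyNA(idx)) stop("hits refer to promoters absent from the table")
  for (i in seq_len(nrow(hits))) {
    pr <- idx[i]
    s <- .encode_seq(promoters$sequence[pr])
    j <- hits$offset[i] - promoters$start_rel[pr] + 1L
    w <- s[j:(j + L - 1L)]
    if (hits$strand[i] == "-") w <- .revcomp_enc(w)
    ok <- !is.na(w)
    counts[cbind(which(ok), w[ok])] <- counts[cbind(which(ok), w[ok])] + 1L
  }
  counts
}

#' Write / read a hit table as TSV
#'
#' @param hits hit data.frame.
#' @param file path.
#' @return `read_hits` returns the hit data.frame.
#' @export
write_hits <- function(hits, file) {
  utils::write.table(hits, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_hits
#' @export
read_hits <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
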