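## nCounter-style count processing: negative-control background
## correction, stable reference selection, geometric-mean normalization,
## repression calling and exact Fisher dependence tests.

#' Construct an nCounter run
#'
#' @param counts non-negative numeric gene x sample matrix (rownames =
#'   genes, colnames = samples).
#' @param gene_roles named character vector mapping every gene to one of
#'   `"target"`, `"negative_control"`, `"reference_candidate"`.
#' @param sample_meta data.frame with rownames (or a `sample` column)
#'   matching `colnames(counts)` and columns `cell_line`, `treatment`,
#'   `replicate`.
#' @return object of class `ncounter_run`: list with `counts`, `roles`,
#'   `meta`, and (after processing) `corrected`, `normalized`,
#'   `references`, `bg_threshold`, `scale`.
#' @export
ncounter_run <- function(counts, gene_roles, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts need gene rownames")
  roles <- gene_roles[rownames(counts)]
  if (anyNA(roles))
    stop("gene_roles missing for: ",
         paste(utils::head(rownames(counts)[is.na(roles)], 5L),
               collapse = ", "))
  ok <- c("target", "negative_control", "reference_candidate")
  if (!all(roles %in% ok))
    stop("gene roles must be one of: ", paste(ok, collapse = ", "))
  if (sum(roles == "negative_control") < 1L)
    stop("at least one negative control is required")
  if (sum(roles == "reference_candidate") < 2L)
    stop("at least two reference candidates are required")
  if (!is.null(sample_meta)) {
    if (!is.null(sample_meta$sample))
      rownames(sample_meta) <- sample_meta$sample
    sample_meta <- sample_meta[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, roles = roles, meta = sample_meta,
                 corrected = NULL, normalized = NULL, references = NULL,
                 bg_threshold = NULL, scale = NULL),
            class = "ncounter_run")
}

#' Background-correct an nCounter run
#'
#' Per sample, the background threshold is the mean plus two standard
#' deviations (sample SD, n-1 denominator) of the negative-control
#' counts; that threshold is subtracted from every gene's count in the
#' sample and the result clamped at zero.
#'
#' @param run an [ncounter_run].
#' @return the run with `corrected` and per-sample `bg_threshold` filled.
#' @export
background_correct <- function(run) {
  stopifnot(inherits(run, "ncounter_run"))
  neg <- run$counts[run$roles == "negative_control", , drop = FALSE]
  if (nrow(neg) < 2L)
    stop("background correction needs >= 2 negative controls per sample")
  thr <- apply(neg, 2L, function(x) mean(x) + 2 * stats::sd(x))
  run$bg_threshold <- thr
  run$corrected <- pmax(sweep(run$counts, 2L, thr, "-"), 0)
  run
}

#' Select the most stable reference genes
#'
#' Stability is measured as the coefficient of variation of
#' `log2(corrected + 1)` across samples; the `k` candidates with the
#' smallest CV are selected (ties broken by gene id).
#'
#' @param run a background-corrected [ncounter_run].
#' @param k number of references to select (default 7).
#' @return character vector of `k` gene ids.
#' @export
select_stable_references <- function(run, k = 7L) {
  stopifnot(inherits(run, "ncounter_run"))
  if (is.null(run$corrected)) run <- background_correct(run)
  cand <- rownames(run$counts)[run$roles == "reference_candidate"]
  if (k > length(cand))
    stop("k = ", k, " exceeds the ", length(cand),
         " reference candidates")
  lc <- log2(run$corrected[cand, , drop = FALSE] + 1)
  m <- rowMeans(lc)
  cv <- ifelse(m > 0, apply(lc, 1L, stats::sd) / m, Inf)
  cand[order(cv, cand)][seq_len(k)]
}

#' Normalize to the geometric mean of the reference genes
#'
#' Per sample the geometric mean `g_s` of the reference counts is taken;
#' each sample is rescaled by `mean(g) / g_s` so that all samples end
#' with the same reference geometric mean while counts stay on their
#' original overall scale.
#'
#' @param run a background-corrected [ncounter_run].
#' @param references reference gene ids; every one must have corrected
#'   count > 0 in every sample.
#' @return the run with `normalized`, `references` and per-sample `scale`
#'   filled.
#' @export
reference_normalize <- function(run, references) {
  stopifnot(inherits(run, "ncounter_run"))
  if (is.null(run$corrected)) run <- background_correct(run)
  ref <- run$corrected[references, , drop = FALSE]
  bad <- which(ref <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("reference '", references[bad[1, 1]], "' has corrected count 0 ",
         "in sample '", colnames(ref)[bad[1, 2]], "'")
  g <- exp(colMeans(log(ref)))
  scale <- mean(g) / g
  run$normalized <- sweep(run$corrected, 2L, scale, "*")
  run$references <- references
  run$scale <- scale
  run
}

#' Full nCounter normalization pipeline
#'
#' Background-corrects, selects the `k` most stable reference candidates
#' and normalizes to their geometric mean.
#'
#' @param run an [ncounter_run].
#' @param k number of reference genes (default 7).
#' @return processed run.
#' @export
normalize_ncounter <- function(run, k = 7L) {
  run <- background_correct(run)
  refs <- select_stable_references(run, k)
  reference_normalize(run, refs)
}

#' Call repression between treatment and mock samples
#'
#' A gene is called repressed when its mean normalized expression in the
#' treated samples is reduced by more than `threshold` relative to the
#' mock mean: `(mean_mock - mean_treated) / mean_mock > threshold`.
#' Genes with zero mock mean get an `NA` call with a warning.
#'
#' @param run a normalized [ncounter_run] (or any gene x sample matrix).
#' @param treated,mock sample (column) names of the two conditions;
#'   replicates are averaged within condition.
#' @param threshold fractional reduction required (default 0.20).
#' @param genes genes to call (default: target genes of the run, or all
#'   rows for a bare matrix).
#' @return named logical vector (`NA` where undefined).
#' @export
call_repression <- function(run, treated, mock, threshold = 0.20,
                            genes = NULL) {
  if (inherits(run, "ncounter_run")) {
    mat <- run$normalized
    if (is.null(mat)) stop("run is not normalized yet")
    if (is.null(genes)) genes <- rownames(mat)[run$roles == "target"]
  } else {
    mat <- as.matrix(run)
    if (is.null(genes)) genes <- rownames(mat)
  }
  mt <- rowMeans(mat[genes, treated, drop = FALSE])
  mm <- rowMeans(mat[genes, mock, drop = FALSE])
  out <- (mm - mt) / mm > threshold
  if (any(mm == 0)) {
    warning("mock mean is 0 for ", sum(mm == 0),
            " gene(s); repression call undefined")
    out[mm == 0] <- NA
  }
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by full enumeration over all tables with the observed margins:
#' the two-sided p-value is the sum of hypergeometric probabilities of
#' all tables whose probability does not exceed that of the observed
#' table (within relative tolerance `1 + 1e-7`), the minimum-likelihood
#' convention.
#'
#' @param x 2x2 matrix of non-negative integer counts, or the count `a`
#'   when `b`, `c`, `d` are given.
#' @param b,c,d remaining cells (row-wise) when `x` is scalar.
#' @return object of class `htest` with the p-value, the sample odds
#'   ratio `(ad)/(bc)` and the input table.
#' @examples
#' fisher_exact(matrix(c(11, 8, 2, 19), 2, byrow = TRUE))$p.value
#' @export
fisher_exact <- function(x, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == 2L))
    a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  } else {
    a <- x
    if (is.null(b) || is.null(c) || is.null(d))
      stop("supply a 2x2 matrix or all four cells")
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) < 1) stop("table total must be >= 1")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  tab <- matrix(cells, 2L, byrow = TRUE,
                dimnames = list(c("class1", "class2"), c("yes", "no")))
  structure(list(
    statistic = NULL, parameter = NULL, p.value = p,
    estimate = c(`odds ratio` = or),
    method = "Two-sided Fisher exact test (minimum-likelihood enumeration)",
    data.name = paste(cells, collapse = ", "),
    table = tab
  ), class = "htest")
}

#' @export
print.ncounter_run <- function(x, ...) {
  cat("nCounter run:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("  roles:", sum(x$roles == "target"), "targets,",
      sum(x$roles == "negative_control"), "negative controls,",
      sum(x$roles == "reference_candidate"), "reference candidates\n")
  if (!is.null(x$bg_threshold))
    cat("  background thresholds:",
        paste(signif(x$bg_threshold, 4), collapse = ", "), "\n")
  if (!is.null(x$references))
    cat("  normalized to", length(x$references), "references:",
        paste(x$references, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ncounter_run <- function(object, ...) {
  print(object)
  if (!is.null(object$normalized)) {
    cat("  per-sample scale factors:",
        paste(signif(object$scale, 4), collapse = ", "), "\n")
  }
  invisible(object)
}

#' Read an nCounter run from TSV sidecar files
#'
#' @param counts_file gene x sample TSV (first column = gene id).
#' @param roles_file two-column TSV `gene`, `role`.
#' @param meta_file optional TSV with `sample`, `cell_line`, `treatment`,
#'   `replicate`.
#' @return an [ncounter_run].
#' @export
read_ncounter_tsv <- function(counts_file, roles_file, meta_file = NULL) {
  cnt <- utils::read.table(counts_file, header = TRUE, sep = "\t",
                           row.names = 1L, check.names = FALSE)
  roles <- utils::read.table(roles_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  meta <- if (!is.null(meta_file))
    utils::read.table(meta_file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  ncounter_run(as.matrix(cnt),
               stats::setNames(roles[[2L]], roles[[1L]]), meta)
}

#' Write normalized counts and repression calls as TSV
#'
#' @param run processed [ncounter_run].
#' @param normalized_file,calls_file output paths (either may be `NULL`).
#' @param calls optional named logical vector from [call_repression()].
#' @export
write_ncounter_tsv <- function(run, normalized_file = NULL,
                               calls_file = NULL, calls = NULL) {
  if (!is.null(normalized_file)) {
    df <- data.frame(gene = rownames(run$normalized), run$normalized,
                     check.names = FALSE)
    utils::write.table(df, normalized_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(calls_file) && !is.null(calls)) {
    utils::write.table(data.frame(gene = names(calls), repressed = calls),
                       calls_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(run)
}
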