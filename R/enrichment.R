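## Per-promoter site-count enrichment statistics.
##
## The headline statistic compares per-promoter counts of predicted sites
## between a regulated gene set (foreground) and background promoters with
## a two-sided Mann-Whitney-Wilcoxon test; enrichment is reported as
## log2(d/b), the log fold-ratio of mean sites per promoter.

#' Count sites per gene within a TSS-relative window
#'
#' @param hits thresholded hit table (see [scan_sequence()]), any mix of
#'   matrices; filter by `matrix_id` before calling if needed.
#' @param genes gene ids of the owning set; every one appears in the
#'   result (zero counts included).
#' @param window TSS-relative half-open interval `(start, end)`; hits with
#'   `offset` outside it are excluded. Default `c(-600, 100)`.
#' @return named integer vector, one entry per gene.
#' @export
count_sites <- function(hits, genes, window = c(-600L, 100L)) {
  keep <- hits$promoter_id %in% genes &
    hits$offset >= window[1] & hits$offset < window[2]
  tab <- table(factor(hits$promoter_id[keep], levels = genes))
  stats::setNames(as.integer(tab), genes)
}

#' Foreground-vs-background site-count enrichment for one matrix
#'
#' Two-sided Mann-Whitney-Wilcoxon comparison of the two per-promoter
#' count vectors: exact enumeration when both sets have at most 8 genes
#' and there are no ties, tie-corrected normal approximation otherwise.
#' `d` and `b` are the mean sites per promoter in foreground and
#' background; enrichment is `log2(d/b)`, undefined (`NA`) when `b = 0`,
#' in which case the shrunk diagnostic `d / (b + 1/n_bg)` is the only
#' ratio reported.
#'
#' @param fg,bg named integer count vectors from [count_sites()]; both
#'   need at least 2 genes.
#' @return list with `p_raw`, `d`, `b`, `enrichment` (log2 d/b),
#'   `enrichment_shrunk` (log2 of the shrunk ratio), `n_fg`,
#'   `genes_with_sites_fg`, `pct_with_sites`.
#' @export
motif_enrichment <- function(fg, bg) {
  if (length(fg) < 2L || length(bg) < 2L)
    stop("both count vectors need at least 2 genes")
  exact <- length(fg) <= 8L && length(bg) <= 8L &&
    !any(duplicated(c(fg, bg)))
  all_tied <- length(unique(c(fg, bg))) == 1L
  p <- if (all_tied) 1 else suppressWarnings(
    stats::wilcox.test(fg, bg, exact = exact, correct = TRUE)$p.value)
  d <- mean(fg); b <- mean(bg)
  list(
    p_raw = p,
    d = d, b = b,
    enrichment = if (b > 0) log2(d / b) else NA_real_,
    enrichment_shrunk = log2(d / (b + 1 / length(bg))),
    n_fg = length(fg),
    genes_with_sites_fg = sum(fg > 0L),
    pct_with_sites = 100 * mean(fg > 0L)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values across the matrix collection, monotone and
#' capped at 1 (delegates to [stats::p.adjust()]).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Apply the overrepresentation pass criteria
#'
#' A matrix passes when all four hold: at least 2-fold enrichment
#' (`log2(d/b) >= 1`), corrected `P < 0.005`, sites present in at least 5
#' foreground promoters, and in at least 25% of them. An undefined
#' enrichment (background mean 0) never passes.
#'
#' @param results data.frame with columns `enrichment`, `p_adj`,
#'   `genes_with_sites_fg`, `pct_with_sites`.
#' @param min_enrichment minimum log2 enrichment (default 1).
#' @param max_p_adj maximum adjusted p (default 0.005).
#' @param min_genes minimum foreground promoters with sites (default 5).
#' @param min_pct minimum percentage of foreground promoters with sites
#'   (default 25).
#' @return `results` with a logical `passes` column set.
#' @export
apply_pass_criteria <- function(results, min_enrichment = 1,
                                max_p_adj = 0.005, min_genes = 5L,
                                min_pct = 25) {
  results$passes <- !is.na(results$enrichment) &
    results$enrichment >= min_enrichment &
    results$p_adj < max_p_adj &
    results$genes_with_sites_fg >= min_genes &
    results$pct_with_sites >= min_pct
  results
}

## default redundancy grouping: factor-name prefix of the matrix id,
## e.g. "V$NFKB_Q6_01" and "V$NFKAPPAB65_01" stay distinct but
## "V$NFKB_Q6" / "V$NFKB_C" collapse to "NFKB"
.default_groups <- function(ids) {
  sub("_.*$", "", sub("^V\\$", "", ids))
}

#' Collapse highly redundant matrices to one representative per group
#'
#' Within each redundancy group the result with the smallest adjusted p is
#' kept (ties: smallest raw p, then matrix id). By default matrices are
#' grouped by the factor-name prefix of their id (text before the first
#' underscore, `V$` stripped); supply `groups` to override, e.g. with a
#' manually curated mapping.
#'
#' @param results enrichment data.frame with `matrix_id`, `p_adj`, `p_raw`.
#' @param groups named character vector mapping `matrix_id` to group label
#'   (default: shared factor-name prefix).
#' @return the surviving rows, one per group, original column set.
#' @export
collapse_redundant <- function(results, groups = NULL) {
  if (is.null(groups)) {
    g <- .default_groups(results$matrix_id)
  } else {
    g <- unname(groups[results$matrix_id])
    g[is.na(g)] <- results$matrix_id[is.na(g)]
  }
  ord <- order(g, results$p_adj, results$p_raw, results$matrix_id)
  r <- results[ord, , drop = FALSE]
  out <- r[!duplicated(g[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full per-matrix enrichment analysis
#'
#' Runs [count_sites()] and [motif_enrichment()] for every matrix in the
#' hit table, adjusts p-values across matrices by Benjamini-Hochberg and
#' applies the pass criteria. This is the statistic behind a
#' Table-1-style summary of overrepresented cis-regulatory elements.
#'
#' @param hits hit table covering all matrices.
#' @param foreground,background disjoint gene-id vectors drawn from the
#'   deduplicated promoter universe.
#' @param window TSS-relative counting window (default `c(-600, 100)`).
#' @param matrices matrix ids to test (default: all in `hits`).
#' @param ... pass-criteria overrides forwarded to [apply_pass_criteria()].
#' @return data.frame of class `motif_enrichment` with one row per matrix:
#'   `matrix_id`, `n_fg`, `genes_with_sites_fg`, `pct_with_sites`, `d`,
#'   `b`, `enrichment`, `enrichment_shrunk`, `p_raw`, `p_adj`, `passes`.
#' @export
motif_enrichment_table <- function(hits, foreground, background,
                                   window = c(-600L, 100L),
                                   matrices = NULL, ...) {
  if (length(intersect(foreground, background)))
    stop("foreground and background gene sets must be disjoint")
  if (is.null(matrices)) matrices <- sort(unique(hits$matrix_id))
  rows <- lapply(matrices, function(m) {
    h <- hits[hits$matrix_id == m, , drop = FALSE]
    fg <- count_sites(h, foreground, window)
    bg <- count_sites(h, background, window)
    c(list(matrix_id = m), motif_enrichment(fg, bg))
  })
  res <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  res <- res[, c("matrix_id", "n_fg", "genes_with_sites_fg",
                 "pct_with_sites", "d", "b", "enrichment",
                 "enrichment_shrunk", "p_raw")]
  res$p_adj <- adjust_fdr(res$p_raw)
  res <- apply_pass_criteria(res, ...)
  attr(res, "window") <- window
  class(res) <- c("motif_enrichment", "data.frame")
  res
}

#' @export
print.motif_enrichment <- function(x, digits = 3, ...) {
  w <- attr(x, "window")
  cat("Motif enrichment:", nrow(x), "matrices, window (",
      w[1], ",", w[2], "),", sum(x$passes), "passing\n")
  df <- as.data.frame(x)
  df$pct_with_sites <- round(df$pct_with_sites, 1)
  for (cc in c("d", "b", "enrichment", "enrichment_shrunk"))
    df[[cc]] <- signif(df[[cc]], digits)
  df$p_raw <- signif(df$p_raw, 2)
  df$p_adj <- signif(df$p_adj, 2)
  print.data.frame(df[order(df$p_adj), ], row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.motif_enrichment <- function(object, ...) {
  passing <- object[object$passes, , drop = FALSE]
  cat(nrow(object), "matrices tested;", nrow(passing),
      "pass (>= 2-fold, adj. P < 0.005, >= 5 promoters, >= 25%)\n")
  if (nrow(passing))
    print.data.frame(passing[order(passing$p_adj),
      c("matrix_id", "pct_with_sites", "enrichment", "p_adj")],
      row.names = FALSE)
  invisible(passing)
}

#' Select significantly regulated genes from a differential table
#'
#' The selection rule is `|log2fc| > log2(min_fold)` and adjusted
#' `P < max_p`, optionally restricted by direction.
#'
#' @param table data.frame with at least `gene_id`, `log2fc`, `p_adj`.
#' @param min_fold minimum fold change (default 2; strict inequality).
#' @param max_p maximum adjusted p (default 0.01; strict inequality).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of unique gene ids.
#' @export
select_regulated <- function(table, min_fold = 2, max_p = 0.01,
                             direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  lfc <- table$log2fc
  sel <- abs(lfc) > log2(min_fold) & table$p_adj < max_p
  sel <- sel & switch(direction, both = TRUE, up = lfc > 0, down = lfc < 0)
  unique(table$gene_id[sel & !is.na(sel)])
}

#' Cumulative positional profile of sites upstream of the TSS
#'
#' For each bin boundary `D` in `bin, 2*bin, ..., depth` the cumulative
#' value is the fraction of genes with at least one site within `D` bp
#' upstream of the TSS (sites downstream of the TSS count at distance 0).
#' The background curve uses the randomly chosen background genes and the
#' `diff` curve is their elementwise difference, which highlights relative
#' positional enrichment.
#'
#' @param hits hit table over deep upstream regions (one matrix).
#' @param foreground,background gene-id vectors.
#' @param bin bin width in bp (default 200).
#' @param depth profiling depth in bp (default 20000).
#' @return object of class `positional_profile`: list with `matrix_id`,
#'   `breaks` (bin boundaries), `cum_fg`, `cum_bg`, `diff`.
#' @export
positional_profile <- function(hits, foreground, background,
                               bin = 200L, depth = 20000L) {
  breaks <- seq(bin, depth, by = bin)
  mid <- unique(hits$matrix_id)
  if (length(mid) > 1L) stop("positional_profile expects a single matrix")
  cum_curve <- function(genes) {
    keep <- hits$promoter_id %in% genes
    dist <- pmax(0L, -hits$offset[keep])
    nearest <- tapply(dist, factor(hits$promoter_id[keep], levels = genes),
                      min)
    vapply(breaks, function(D)
      sum(!is.na(nearest) & nearest <= D) / length(genes), 0)
  }
  cf <- cum_curve(foreground)
  cb <- cum_curve(background)
  structure(list(matrix_id = if (length(mid)) mid else NA_character_,
                 breaks = breaks, cum_fg = cf, cum_bg = cb,
                 diff = cf - cb),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("Positional profile", x$matrix_id, ": bins of",
      x$breaks[1], "bp to", max(x$breaks), "bp upstream\n")
  cat("  final cumulative fg =", round(utils::tail(x$cum_fg, 1), 3),
      ", bg =", round(utils::tail(x$cum_bg, 1), 3), "\n")
  cat("  max |diff| =", round(max(abs(x$diff)), 3), "at",
      x$breaks[which.max(abs(x$diff))], "bp\n")
  invisible(x)
}

#' @export
plot.positional_profile <- function(x, which = c("cumulative", "diff"),
                                    ...) {
  which <- match.arg(which)
  if (which == "cumulative") {
    graphics::plot(x$breaks, 100 * x$cum_fg, type = "l", col = "firebrick",
                   xlab = "distance upstream of TSS (bp)",
                   ylab = "% genes with site",
                   main = x$matrix_id, ylim = c(0, 100), ...)
    graphics::lines(x$breaks, 100 * x$cum_bg, lty = 2, col = "grey40")
    graphics::legend("bottomright", c("regulated", "random background"),
                     col = c("firebrick", "grey40"), lty = c(1, 2),
                     bty = "n")
  } else {
    graphics::plot(x$breaks, 100 * x$diff, type = "l", col = "firebrick",
                   xlab = "distance upstream of TSS (bp)",
                   ylab = "% regulated - % background",
                   main = x$matrix_id, ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Induction strength vs element presence cross-tabulation
#'
#' For each regulation stratum (e.g. a time window) and each fold cut,
#' reports the percentage of genes induced beyond that cut whose promoter
#' carries at least one site of each element. Empty strata are `NA` with
#' a warning.
#'
#' @param table regulated-gene table with `gene_id`, `time_window`,
#'   `log2fc`.
#' @param element_sites named list of site-count vectors (one per element;
#'   see [count_sites()]).
#' @param fold_cuts induction-strength cuts (default `c(2, 4, 8, 16)`,
#'   interpreted as strictly-greater fold inductions).
#' @return data.frame with `time_window`, `fold_cut`, `n_genes`, one
#'   percentage column per element.
#' @export
strength_time_crosstab <- function(table, element_sites,
                                   fold_cuts = c(2, 4, 8, 16)) {
  windows <- unique(table$time_window)
  grid <- expand.grid(time_window = windows, fold_cut = fold_cuts,
                      stringsAsFactors = FALSE)
  pct <- matrix(NA_real_, nrow(grid), length(element_sites),
                dimnames = list(NULL, names(element_sites)))
  n_genes <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sel <- table$time_window == grid$time_window[i] &
      table$log2fc > log2(grid$fold_cut[i])
    genes <- unique(table$gene_id[sel])
    n_genes[i] <- length(genes)
    if (!length(genes)) {
      warning("no genes above ", grid$fold_cut[i], "-fold in stratum '",
              grid$time_window[i], "'", call. = FALSE)
      next
    }
    for (e in names(element_sites))
      pct[i, e] <- 100 * mean(element_sites[[e]][genes] > 0L,
                              na.rm = TRUE)
  }
  cbind(grid, n_genes = n_genes, as.data.frame(pct))
}

#' Cooperativity of element copy number and induction strength
#'
#' Genes are classed by the number of sites in their promoter (0, 1, >1)
#' and the median induction of each class is reported, together with a
#' two-sided Spearman rank correlation between raw site count and log2
#' fold change.
#'
#' @param site_counts named site-count vector (see [count_sites()]).
#' @param log2fc named log2 fold-change vector (names matched to
#'   `site_counts`).
#' @return list with `medians` (named `"0"`, `"1"`, `">1"`), `n` per
#'   class, `rho` and `p` (Spearman; `p = 1` when either variable is
#'   constant).
#' @export
cooperativity <- function(site_counts, log2fc) {
  genes <- intersect(names(site_counts), names(log2fc))
  if (length(genes) < 3L) stop("need at least 3 genes in common")
  k <- site_counts[genes]
  f <- log2fc[genes]
  cls <- cut(k, breaks = c(-0.5, 0.5, 1.5, Inf), labels = c("0", "1", ">1"))
  med <- tapply(f, cls, stats::median)
  n <- as.integer(table(cls))
  if (stats::sd(k) == 0 || stats::sd(f) == 0) {
    rho <- 0; p <- 1
  } else {
    ct <- suppressWarnings(
      stats::cor.test(k, f, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  list(medians = med, n = stats::setNames(n, levels(cls)), rho = rho, p = p)
}

#' Per-gene normalization of a log2 time-course matrix
#'
#' Centres each gene's log2 expression row on its own mean, so curves show
#' deviation from the gene's time-course average; `method = "zscore"`
#' additionally divides by the row standard deviation.
#'
#' @param mat numeric gene x timepoint matrix of log2 expression values.
#' @param method `"center"` (default) or `"zscore"`.
#' @return matrix of the same shape; every row of the centred output sums
#'   to zero.
#' @export
per_gene_normalize <- function(mat, method = c("center", "zscore")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  out <- sweep(mat, 1L, rowMeans(mat), "-")
  if (method == "zscore") {
    sds <- apply(mat, 1L, stats::sd)
    sds[sds == 0] <- 1
    out <- sweep(out, 1L, sds, "/")
  }
  out
}

#' Time-course heat map of per-gene normalized expression
#'
#' Thin rendering utility: rows (genes) are ordered by complete-linkage
#' hierarchical clustering of Euclidean distances; columns stay in
#' time-course order.
#'
#' @param mat gene x timepoint matrix (typically [per_gene_normalize()]
#'   output).
#' @param ... forwarded to [stats::heatmap()].
#' @export
plot_timecourse_heatmap <- function(mat, ...) {
  stats::heatmap(as.matrix(mat), Colv = NA,
                 hclustfun = function(d) stats::hclust(d, "complete"),
                 distfun = stats::dist, scale = "none",
                 col = grDevices::hcl.colors(64, "Blue-Yellow"), ...)
}
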