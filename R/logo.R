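## A-posteriori sequence logo rendering from matched-window base counts.

#' Plot an information-content logo from a base count matrix
#'
#' Renders the per-position information content (bits) of the observed
#' base counts under the matched windows (see [logo_counts()]) as stacked
#' bars, each base's share proportional to its frequency. A minimal base
#' graphics rendering: letters are drawn as coloured stacked rectangles
#' with the base character inside.
#'
#' @param counts L x 4 count matrix (columns A, C, G, T).
#' @param main plot title.
#' @export
plot_logo <- function(counts, main = "") {
  counts <- as.matrix(counts)
  L <- nrow(counts)
  tot <- rowSums(counts)
  if (all(tot == 0)) {
    warning("empty count matrix; nothing to plot")
    return(invisible(NULL))
  }
  f <- counts / pmax(tot, 1)
  ## information content in bits, log2 scale with 0 log 0 := 0
  ic <- apply(f, 1L, function(p) {
    nz <- p > 0
    2 + sum(p[nz] * log2(p[nz]))
  })
  ic[tot == 0] <- 0
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  graphics::plot(NULL, xlim = c(0.5, L + 0.5), ylim = c(0, 2),
                 xlab = "position", ylab = "bits", main = main,
                 xaxs = "i", yaxs = "i")
  for (i in seq_len(L)) {
    ord <- order(f[i, ])            # smallest at the bottom
    y <- 0
    for (b in ord) {
      h <- f[i, b] * ic[i]
      if (h <= 0) next
      graphics::rect(i - 0.45, y, i + 0.45, y + h, col = cols[b],
                     border = NA)
      if (h > 0.12)
        graphics::text(i, y + h / 2, DNA_BASES[b], col = "white",
                       cex = min(1.2, 0.4 + h))
      y <- y + h
    }
  }
  invisible(ic)
}
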