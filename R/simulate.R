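## Synthetic-data generators. Every input the pipeline consumes can be
## produced here with a known ground-truth manifest, fully determined by
## the seed, so each statistical stage is testable without downloads.

#' Default synthetic motif matrices
#'
#' A small collection of sharp TFBS-like count matrices used by the
#' simulators: an ISRE-like 12-mer, a GAS-like palindromic 13-mer
#' (TTC-N3-GAA core) and an NF-kB-like 10-mer. Consensus bases carry 91%
#' of the counts per position (3% each for the others), giving
#' high-information columns comparable to curated vertebrate TFBS models;
#' `N`-like spacer positions are uniform.
#'
#' @return named list of [pwm] objects.
#' @export
default_motif_matrices <- function() {
  build <- function(id, factor, consensus, strong = 0.91) {
    b <- strsplit(consensus, "")[[1L]]
    counts <- matrix(0, length(b), 4L)
    for (i in seq_along(b)) {
      if (b[i] == "N") counts[i, ] <- 25
      else {
        counts[i, ] <- round(100 * (1 - strong) / 3)
        counts[i, match(b[i], DNA_BASES)] <- round(100 * strong)
      }
    }
    pwm(counts, matrix_id = id, factor_name = factor)
  }
  list(
    ISRE_SYN = build("ISRE_SYN", "V$ISRE_SYN", "AGTTTCACTTTC"),
    GAS_SYN  = build("GAS_SYN",  "V$GAS_SYN",  "TTCCNNNGGAA"),
    NFKB_SYN = build("NFKB_SYN", "V$NFKB_SYN", "GGGACTTTCC")
  )
}

#' Simulate a TRANSFAC-style matrix collection
#'
#' Random count matrices with unique accessions, for parser round-trip
#' and scanning stress tests. Each position draws a dominant base with
#' weight `sharpness` and distributes the rest uniformly.
#'
#' @param n number of matrices.
#' @param length_range inclusive range of matrix lengths.
#' @param sharpness consensus base frequency (default 0.85).
#' @param total counts per position (default 100).
#' @param seed RNG seed.
#' @return named list of [pwm] objects with ids `M00001`, ...
#' @export
simulate_matrices <- function(n, length_range = c(8L, 16L),
                              sharpness = 0.85, total = 100L, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(length_range[1]:length_range[2], 1L)
    counts <- matrix(0, L, 4L)
    for (j in seq_len(L)) {
      dom <- sample.int(4L, 1L)
      counts[j, ] <- round(total * (1 - sharpness) / 3)
      counts[j, dom] <- round(total * sharpness)
    }
    id <- sprintf("M%05d", i)
    out[[i]] <- pwm(counts, matrix_id = id,
                    factor_name = sprintf("V$SYN%05d", i))
  }
  stats::setNames(out, vapply(out, `[[`, "", "matrix_id"))
}

## i.i.d. DNA at the stated GC content
.random_dna <- function(n, gc = 0.42) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a genome with a non-overlapping TSS annotation
#'
#' One contig of i.i.d. bases at the stated GC content, with `n_genes`
#' TSSs spaced at least a full extraction window apart and strands
#' alternating, so every promoter is extractable and untruncated.
#'
#' @param n_genes number of genes.
#' @param window the extraction window the spacing must accommodate
#'   (default `c(-600, 100)`).
#' @param gc GC content in `[0, 1]` (default 0.42, mammalian-like).
#' @param spacing extra bp between consecutive gene windows (default 100).
#' @param seed RNG seed.
#' @return list with `genome` (named character, contig `chr1`) and `tss`
#'   (data.frame `gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_genome <- function(n_genes, window = c(-600L, 100L), gc = 0.42,
                            spacing = 100L, seed = 1L) {
  set.seed(seed)
  span <- window[2] - window[1]
  ## a window can extend up to max(|start|, |end|) bp to either genomic
  ## side of the TSS depending on strand; spacing TSSs twice that apart
  ## keeps neighbouring windows disjoint whatever the strands
  reach <- max(abs(window))
  slot <- 2L * reach + spacing
  margin <- reach + spacing
  len <- margin + n_genes * slot + margin
  genome <- c(chr1 = .random_dna(len, gc))
  tss_pos <- margin + (seq_len(n_genes) - 1L) * slot + span %/% 2L
  tss <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chrom = "chr1",
    tss = as.integer(tss_pos),
    strand = rep_len(c("+", "-"), n_genes),
    stringsAsFactors = FALSE
  )
  list(genome = genome, tss = tss)
}

#' Simulate bare promoter sequences
#'
#' Direct construction of a `promoter_set` of i.i.d. sequences in the
#' given TSS-relative window, bypassing genome extraction; the fast route
#' for planted-motif experiments where only the promoter frame matters.
#'
#' @param n number of promoters.
#' @param window TSS-relative window (default `c(-600, 100)`).
#' @param gc GC content (default 0.42).
#' @param prefix gene-id prefix.
#' @param seed RNG seed.
#' @return a `promoter_set` data.frame.
#' @export
simulate_promoters <- function(n, window = c(-600L, 100L), gc = 0.42,
                               prefix = "g", seed = 1L) {
  set.seed(seed)
  span <- window[2] - window[1]
  out <- data.frame(
    gene_id = sprintf("%s%04d", prefix, seq_len(n)),
    chrom = "sim", tss = 0L, strand = "+",
    start = window[1], end = window[2],
    start_rel = window[1], end_rel = window[2],
    truncated = FALSE,
    sequence = vapply(seq_len(n), function(i) .random_dna(span, gc), ""),
    stringsAsFactors = FALSE
  )
  attr(out, "window") <- as.integer(window)
  class(out) <- c("promoter_set", "data.frame")
  out
}

## sample one realisation of the matrix: a base per position from the
## frequency rows
.sample_word <- function(p) {
  L <- nrow(p$frequencies)
  idx <- vapply(seq_len(L), function(i)
    sample.int(4L, 1L, prob = p$frequencies[i, ]), 0L)
  paste(DNA_BASES[idx], collapse = "")
}

#' Plant PWM-sampled motif instances into promoters
#'
#' Per promoter a Poisson(`lambda`) number of instances is sampled from
#' the matrix's frequency rows and written at sampled offsets and strands
#' without overwriting previously planted instances (an instance that
#' cannot be placed after 50 tries is dropped). Offsets are uniform over
#' the window by default; the `"exponential"` positional model draws the
#' upstream distance from an exponential with mean `decay` bp, mimicking
#' TSS-proximal accumulation of real sites.
#'
#' @param promoters a `promoter_set`.
#' @param x the [pwm] to plant.
#' @param lambda mean instances per promoter.
#' @param positional `"uniform"` or `"exponential"`.
#' @param decay mean upstream distance in bp for the exponential model
#'   (default 2000).
#' @param genes subset of gene ids to plant into (default: all).
#' @param seed RNG seed.
#' @return list with `promoters` (modified set) and `manifest`
#'   (data.frame `gene_id`, `matrix_id`, `offset`, `strand`, `seq`).
#' @export
plant_motifs <- function(promoters, x, lambda,
                         positional = c("uniform", "exponential"),
                         decay = 2000, genes = NULL, seed = 1L) {
  stopifnot(inherits(x, "pwm"))
  positional <- match.arg(positional)
  set.seed(seed)
  if (is.null(genes)) genes <- promoters$gene_id
  L <- nrow(x$counts)
  man <- list()
  seqs <- promoters$sequence
  for (gi in match(genes, promoters$gene_id)) {
    k <- stats::rpois(1L, lambda)
    if (k == 0L) next
    lo <- promoters$start_rel[gi]
    hi <- promoters$end_rel[gi] - L        # last legal start offset
    if (hi < lo) next
    occupied <- integer(0)
    for (j in seq_len(k)) {
      placed <- FALSE
      for (try in 1:50) {
        off <- if (positional == "uniform") {
          sample(lo:hi, 1L)
        } else {
          max(lo, min(hi, -as.integer(ceiling(stats::rexp(1L, 1 / decay)))))
        }
        span <- off:(off + L - 1L)
        if (!any(span %in% occupied)) { placed <- TRUE; break }
      }
      if (!placed) next
      occupied <- c(occupied, span)
      word <- .sample_word(x)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") word else revcomp(word)
      pos <- off - lo + 1L
      substr(seqs[gi], pos, pos + L - 1L) <- ins
      man[[length(man) + 1L]] <- data.frame(
        gene_id = promoters$gene_id[gi], matrix_id = x$matrix_id,
        offset = off, strand = strand, seq = word,
        stringsAsFactors = FALSE)
    }
  }
  promoters$sequence <- seqs
  manifest <- if (length(man)) do.call(rbind, man) else
    data.frame(gene_id = character(), matrix_id = character(),
               offset = integer(), strand = character(),
               seq = character())
  list(promoters = promoters, manifest = manifest)
}

#' Simulate a differential-expression table with known truth sets
#'
#' Designated induced/repressed genes get `log2fc ~ N(+/-effect,
#' noise_sd)` and small adjusted p-values; null genes get
#' `log2fc ~ N(0, noise_sd)` and adjusted p-values above the selection
#' cutoff, so membership is consistent with the `>2-fold, P < 0.01`
#' selection rule.
#'
#' @param n_up,n_down,n_null set sizes.
#' @param effect absolute log2 effect size of regulated genes (default 2).
#' @param noise_sd log2 noise SD (default 0.3).
#' @param condition,time_window annotation columns.
#' @param seed RNG seed.
#' @return list with `table` (data.frame `gene_id`, `condition`,
#'   `time_window`, `log2fc`, `p_adj`) and `truth` (list `up`, `down`).
#' @export
simulate_de_table <- function(n_up = 30L, n_down = 20L, n_null = 950L,
                              effect = 2, noise_sd = 0.3,
                              condition = "IFN", time_window = "30-60",
                              seed = 1L) {
  set.seed(seed)
  n <- n_up + n_down + n_null
  ids <- sprintf("g%04d", seq_len(n))
  up <- ids[seq_len(n_up)]
  down <- ids[n_up + seq_len(n_down)]
  lfc <- c(stats::rnorm(n_up, effect, noise_sd),
           stats::rnorm(n_down, -effect, noise_sd),
           stats::rnorm(n_null, 0, noise_sd))
  p <- c(10 ^ -stats::runif(n_up + n_down, 3, 10),
         stats::runif(n_null, 0.02, 1))
  list(table = data.frame(gene_id = ids, condition = condition,
                          time_window = time_window, log2fc = lfc,
                          p_adj = p, stringsAsFactors = FALSE),
       truth = list(up = up, down = down))
}

#' Simulate an nCounter run with planted repression
#'
#' Counts are built as `scale_s * (base_g * effect_gs * lognormal noise)
#' + background`, with background counts Poisson by default (or
#' `N(bg_mean, bg_sd)` clamped at zero when `bg_sd` is given, so that
#' `bg_sd = 0` yields the deterministic zero-noise limit). Negative
#' controls carry background only. Planted repressed targets have their
#' treated-sample signal multiplied by `1 - repression`.
#'
#' @param n_targets number of target genes.
#' @param n_repressed how many targets carry planted repression.
#' @param repression planted fractional repression (default 0.4).
#' @param n_refs reference candidates; `ref_noise_sd` (recycled) is the
#'   extra log-normal noise SD per candidate, so stable and unstable
#'   candidates can be mixed.
#' @param n_neg negative controls (default 6).
#' @param n_reps replicates per condition (default 4).
#' @param cv biological coefficient of variation of the log-normal signal
#'   noise (default 0.1).
#' @param bg_mean mean background count (default 10).
#' @param bg_sd if given, background is normal with this SD instead of
#'   Poisson; `0` makes it deterministic.
#' @param scale_sd SD of log-normal per-sample scale factors (default
#'   0.15; `0` for unit scales).
#' @param base_mean geometric-mean base expression of targets/references.
#' @param ref_noise_sd per-candidate extra noise SD (default 0).
#' @param seed RNG seed.
#' @return list with `run` (an [ncounter_run]) and `truth` (list
#'   `repressed`, `scale`, `base`, `treated`, `mock`).
#' @export
simulate_ncounter_run <- function(n_targets = 40L, n_repressed = 20L,
                                  repression = 0.4, n_refs = 10L,
                                  n_neg = 6L, n_reps = 4L, cv = 0.1,
                                  bg_mean = 10, bg_sd = NULL,
                                  scale_sd = 0.15, base_mean = 500,
                                  ref_noise_sd = 0, seed = 1L) {
  set.seed(seed)
  targets <- sprintf("t%03d", seq_len(n_targets))
  refs <- sprintf("ref%02d", seq_len(n_refs))
  negs <- sprintf("neg%02d", seq_len(n_neg))
  repressed <- targets[seq_len(n_repressed)]
  genes <- c(targets, refs, negs)
  roles <- stats::setNames(
    c(rep("target", n_targets), rep("reference_candidate", n_refs),
      rep("negative_control", n_neg)), genes)

  samples <- c(paste0("mock_", seq_len(n_reps)),
               paste0("ifng_", seq_len(n_reps)))
  treated <- grep("^ifng", samples, value = TRUE)
  mock <- grep("^mock", samples, value = TRUE)
  meta <- data.frame(sample = samples, cell_line = "NIH3T3",
                     treatment = rep(c("mock", "ifng"), each = n_reps),
                     replicate = rep(seq_len(n_reps), 2L),
                     stringsAsFactors = FALSE)

  scale <- if (scale_sd > 0)
    exp(stats::rnorm(length(samples), 0, scale_sd)) else
    rep(1, length(samples))
  names(scale) <- samples

  base <- stats::setNames(
    c(exp(stats::rnorm(n_targets, log(base_mean), 0.8)),
      exp(stats::rnorm(n_refs, log(base_mean * 1.5), 0.4)),
      rep(0, n_neg)), genes)

  sdlog <- sqrt(log(1 + cv^2))
  ref_sd <- rep_len(ref_noise_sd, n_refs)
  bg_draw <- function(n) {
    if (is.null(bg_sd)) stats::rpois(n, bg_mean)
    else pmax(stats::rnorm(n, bg_mean, bg_sd), 0)
  }

  counts <- matrix(0, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (s in samples) {
    eff <- rep(1, length(genes))
    if (s %in% treated)
      eff[match(repressed, genes)] <- 1 - repression
    noise <- exp(stats::rnorm(length(genes), 0, sdlog))
    extra <- rep(1, length(genes))
    if (any(ref_sd > 0))
      extra[match(refs, genes)] <-
        exp(stats::rnorm(n_refs, 0, ref_sd))
    counts[, s] <- scale[s] * (base * eff * noise * extra + bg_draw(length(genes)))
  }
  run <- ncounter_run(counts, roles, meta)
  list(run = run,
       truth = list(repressed = repressed, scale = scale, base = base,
                    treated = treated, mock = mock))
}

#' End-to-end planted-motif enrichment experiment
#'
#' Generates foreground and background promoter sets, plants instances of
#' one matrix at the two stated densities, scans both sets and runs the
#' enrichment statistic — the full sequence-level pipeline on ground-truth
#' data. Defaults are the reference study conditions: foreground density
#' 2.0 and background density 0.5 planted sites per promoter, 60
#' foreground vs 1000 background promoters.
#'
#' @param x the [pwm] to plant and scan (default: the ISRE-like synthetic
#'   matrix).
#' @param lambda_fg,lambda_bg planted densities (sites/promoter).
#' @param n_fg,n_bg set sizes.
#' @param window promoter window (default `c(-600, 100)`).
#' @param gc background GC content (default 0.42).
#' @param thresholds scan thresholds.
#' @param seed RNG seed.
#' @return list with `result` (single-row [motif_enrichment_table()]
#'   output), `hits`, `manifest` (combined plant manifest), `fg`, `bg`
#'   (gene ids), `promoters`.
#' @export
simulate_enrichment_experiment <- function(x = default_motif_matrices()$ISRE_SYN,
                                           lambda_fg = 2.0,
                                           lambda_bg = 0.5,
                                           n_fg = 60L, n_bg = 1000L,
                                           window = c(-600L, 100L),
                                           gc = 0.42,
                                           thresholds = scan_thresholds(),
                                           seed = 1L) {
  fg_prom <- simulate_promoters(n_fg, window, gc, prefix = "fg",
                                seed = seed)
  bg_prom <- simulate_promoters(n_bg, window, gc, prefix = "bg",
                                seed = seed + 1L)
  fg_pl <- plant_motifs(fg_prom, x, lambda_fg, seed = seed + 2L)
  bg_pl <- plant_motifs(bg_prom, x, lambda_bg, seed = seed + 3L)
  prom <- rbind(fg_pl$promoters, bg_pl$promoters)
  attr(prom, "window") <- as.integer(window)
  class(prom) <- c("promoter_set", "data.frame")
  hits <- scan_promoters(x, prom, thresholds)
  res <- motif_enrichment_table(hits, fg_pl$promoters$gene_id,
                                bg_pl$promoters$gene_id, window,
                                matrices = x$matrix_id)
  list(result = res, hits = hits,
       manifest = rbind(fg_pl$manifest, bg_pl$manifest),
       fg = fg_pl$promoters$gene_id, bg = bg_pl$promoters$gene_id,
       promoters = prom)
}
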