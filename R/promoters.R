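## Promoter extraction: TSS-anchored, gene-oriented windows.
##
## Coordinates are 0-based half-open throughout. TSS-relative position 0 is
## the TSS base itself; upstream positions are negative. For a minus-strand
## gene the TSS-relative frame runs along the reverse complement.

#' Read a TSS table from BED6
#'
#' The interval's strand-aware 5' end is taken as the TSS: `chromStart`
#' for `+` records, `chromEnd - 1` for `-` records. The `name` column is
#' the gene id; `score` is ignored.
#'
#' @param file BED6 path.
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
read_tss_bed <- function(file) {
  bed <- utils::read.table(file, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stop("BED6 input needs 6 columns")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(bed$strand %in% c("+", "-")))
    stop("BED strand column must be '+' or '-'")
  data.frame(gene_id = bed$name, chrom = bed$chrom,
             tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             strand = bed$strand, stringsAsFactors = FALSE)
}

#' Write a TSS table as BED6
#'
#' @param tss TSS data.frame (`gene_id`, `chrom`, `tss`, `strand`).
#' @param file output path.
#' @export
write_tss_bed <- function(tss, file) {
  bed <- data.frame(chrom = tss$chrom,
                    start = ifelse(tss$strand == "+", tss$tss, tss$tss),
                    end = tss$tss + 1L,
                    name = tss$gene_id, score = 0L, strand = tss$strand)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

## Accepts a named character vector or a Biostrings::DNAStringSet
.as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector or DNAStringSet")
  ## FASTA headers may carry descriptions: keep the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a genome FASTA into a named character vector
#'
#' @param file FASTA path.
#' @return named character vector of contig sequences.
#' @export
read_genome_fasta <- function(file) {
  .as_genome(Biostrings::readDNAStringSet(file))
}

#' Extract gene-oriented promoter windows around annotated TSSs
#'
#' For a `+` strand gene the genomic slice is
#' `[tss + start_rel, tss + end_rel)`; for a `-` strand gene it is the
#' reverse complement of `[tss - end_rel + 1, tss - start_rel + 1)`. In
#' both cases TSS-relative position 0 of the returned sequence is the TSS
#' base. Slices clipped at contig ends are flagged `truncated` and keep
#' their achieved relative coordinates.
#'
#' @param genome named character vector (or `DNAStringSet`) of contigs.
#' @param tss TSS table (see [read_tss_bed()]).
#' @param window length-2 integer vector `(start_rel, end_rel)`, a
#'   TSS-relative half-open interval; default `c(-600, 100)`.
#' @return data.frame of class `promoter_set` with columns `gene_id`,
#'   `chrom`, `tss`, `strand`, `start`, `end` (genomic, 0-based half-open),
#'   `start_rel`, `end_rel`, `truncated`, `sequence`.
#' @export
extract_promoters <- function(genome, tss, window = c(-600L, 100L)) {
  genome <- .as_genome(genome)
  stopifnot(length(window) == 2L, window[1] < window[2])
  missing <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing))
    stop("chromosomes absent from genome: ", paste(missing, collapse = ", "))
  clen <- nchar(genome)[tss$chrom]

  outside <- tss$tss < 0L | tss$tss >= clen
  if (any(outside)) {
    warning("skipping ", sum(outside), " TSS record(s) outside contig: ",
            paste(utils::head(tss$gene_id[outside], 5L), collapse = ", "))
    tss <- tss[!outside, , drop = FALSE]
    clen <- clen[!outside]
  }

  plus <- tss$strand == "+"
  a <- ifelse(plus, tss$tss + window[1], tss$tss - window[2] + 1L)
  b <- ifelse(plus, tss$tss + window[2], tss$tss - window[1] + 1L)
  ca <- pmax(a, 0L)
  cb <- pmin(b, clen)
  truncated <- ca != a | cb != b

  seqs <- substr(genome[tss$chrom], ca + 1L, cb)
  seqs[!plus] <- vapply(seqs[!plus], revcomp, "", USE.NAMES = FALSE)

  start_rel <- ifelse(plus, ca - tss$tss, tss$tss - cb + 1L)
  end_rel <- ifelse(plus, cb - tss$tss, tss$tss - ca + 1L)

  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                    tss = tss$tss, strand = tss$strand,
                    start = as.integer(ca), end = as.integer(cb),
                    start_rel = as.integer(start_rel),
                    end_rel = as.integer(end_rel),
                    truncated = truncated, sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  attr(out, "window") <- as.integer(window)
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Extract deep upstream regions
#'
#' Same frame as [extract_promoters()] with window `(-depth, +100)`;
#' used for positional profiling of sites up to `depth` bp upstream of
#' the TSS.
#'
#' @inheritParams extract_promoters
#' @param depth upstream extent in bp (default 20000).
#' @export
extract_upstream_regions <- function(genome, tss, depth = 20000L) {
  extract_promoters(genome, tss, window = c(-as.integer(depth), 100L))
}

#' Discard overlapping and redundant promoters, keeping one per gene
#'
#' First one record per `gene_id` is kept (the one whose genomic window
#' starts leftmost; first occurrence on ties). Then, sweeping each
#' chromosome left to right, any record whose genomic window overlaps an
#' already-kept record is discarded, so the survivor of an overlapping
#' pair is the record with the leftmost window start (ties broken
#' lexicographically by `gene_id`). The result is pairwise non-overlapping
#' and one-per-gene.
#'
#' @param promoters a `promoter_set` from [extract_promoters()].
#' @return the surviving `promoter_set`.
#' @export
deduplicate_promoters <- function(promoters) {
  p <- promoters
  ## one per gene: leftmost window start, then input order
  p <- p[order(p$gene_id, p$start), , drop = FALSE]
  p <- p[!duplicated(p$gene_id), , drop = FALSE]
  ## greedy non-overlap sweep per chromosome
  p <- p[order(p$chrom, p$start, p$gene_id), , drop = FALSE]
  keep <- logical(nrow(p))
  last_end <- -Inf
  last_chrom <- ""
  for (i in seq_len(nrow(p))) {
    if (p$chrom[i] != last_chrom || p$start[i] >= last_end) {
      keep[i] <- TRUE
      last_chrom <- p$chrom[i]
      last_end <- p$end[i]
    }
  }
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- attr(promoters, "window")
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Sample a background gene set
#'
#' Uniform sample without replacement from the promoter universe minus the
#' foreground, reproducible under `seed`.
#'
#' @param universe character vector of gene ids (deduplicated universe).
#' @param foreground gene ids excluded from sampling.
#' @param n sample size.
#' @param seed integer RNG seed (required for reproducibility).
#' @return character vector of `n` gene ids.
#' @export
sample_background <- function(universe, foreground, n, seed) {
  pool <- setdiff(universe, foreground)
  if (n > length(pool))
    stop("requested background of ", n, " from a complement of only ",
         length(pool), " genes")
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  sample(pool, n)
}

#' Write promoters as FASTA with `>gene_id|chrom|tss|strand` headers
#'
#' @param promoters a `promoter_set`.
#' @param file output path.
#' @export
write_promoters_fasta <- function(promoters, file) {
  x <- Biostrings::DNAStringSet(promoters$sequence)
  names(x) <- paste(promoters$gene_id, promoters$chrom, promoters$tss,
                    promoters$strand, sep = "|")
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @export
print.promoter_set <- function(x, ...) {
  w <- attr(x, "window")
  cat("Promoter set:", nrow(x), "records, window (",
      w[1], ",", w[2], "), ", sum(x$truncated), "truncated\n")
  print.data.frame(utils::head(as.data.frame(x)[,
    c("gene_id", "chrom", "tss", "strand", "start", "end", "truncated")]),
    ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
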