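test_that("site counting respects the window and zero-fills genes", {
  hits <- data.frame(
    promoter_id = c("a", "a", "a", "b", "c"),
    matrix_id = "M", offset = c(-500L, -100L, 50L, -700L, -599L),
    strand = "+", mss = 1, core_score = 1)
  counts <- count_sites(hits, c("a", "b", "c", "d"))
  expect_equal(counts, c(a = 3L, b = 0L, c = 1L, d = 0L))
  ## boundary: -600 included, +100 excluded
  edge <- data.frame(promoter_id = "a", matrix_id = "M",
                     offset = c(-600L, 100L), strand = "+",
                     mss = 1, core_score = 1)
  expect_equal(count_sites(edge, "a"), c(a = 1L))
})

test_that("counts from a planted fixture match the generator manifest", {
  p <- default_motif_matrices()$NFKB_SYN
  prom <- simulate_promoters(40, seed = 51)
  pl <- plant_motifs(prom, p, 1.5, seed = 52)
  hits <- scan_promoters(p, pl$promoters)
  counts <- count_sites(hits, prom$gene_id)
  ## every exact-consensus plant must be recovered at its offset/strand
  cons <- pl$manifest[pl$manifest$seq == consensus_string(p), ]
  for (i in seq_len(nrow(cons))) {
    expect_true(any(hits$promoter_id == cons$gene_id[i] &
                    hits$offset == cons$offset[i]))
  }
  ## every reported hit re-verified against an independent rescoring
  for (i in seq_len(min(nrow(hits), 50L))) {
    pr <- match(hits$promoter_id[i], pl$promoters$gene_id)
    j <- hits$offset[i] - pl$promoters$start_rel[pr] + 1L
    w <- substr(pl$promoters$sequence[pr], j, j + nrow(p$counts) - 1L)
    if (hits$strand[i] == "-") w <- revcomp(w)
    expect_gte(mss_oracle(p, w), 0.85)
    expect_equal(mss_oracle(p, w), hits$mss[i], tolerance = 1e-12)
  }
})

test_that("the null case and the 4x case behave as designed", {
  fg <- setNames(rep(c(0L, 1L, 2L), each = 4), sprintf("f%02d", 1:12))
  res0 <- motif_enrichment(fg, fg)
  expect_equal(res0$enrichment, 0)
  expect_gte(res0$p_raw, 0.99)
  fg4 <- setNames(rep(4L, 20), sprintf("f%02d", 1:20))
  bg1 <- setNames(rep(1L, 100), sprintf("b%03d", 1:100))
  res <- motif_enrichment(fg4, bg1)
  expect_equal(res$d, 4)
  expect_equal(res$b, 1)
  expect_equal(res$enrichment, 2)
  expect_equal(res$pct_with_sites, 100)
  expect_error(motif_enrichment(fg4[1], bg1), "at least 2")
})

test_that("exact branch matches the rank-sum enumeration oracle", {
  ## exact enumeration is used when both sizes are <= 8 and untied
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    u <- sample(0:(n * m), 1)
    s <- samples_with_u(u, n, m)
    got <- motif_enrichment(setNames(s$x, paste0("f", seq_len(n))),
                            setNames(s$y, paste0("b", seq_len(m))))$p_raw
    expect_equal(got, exact_mww_p(u, n, m), tolerance = 1e-12)
  }
})

test_that("enrichment is antisymmetric under set swap", {
  set.seed(62)
  for (rep in 1:10) {
    fg <- setNames(rpois(30, 2), paste0("f", 1:30))
    bg <- setNames(rpois(80, 1), paste0("b", 1:80))
    if (mean(bg) == 0 || mean(fg) == 0) next
    a <- motif_enrichment(fg, bg)
    b <- motif_enrichment(bg, fg)
    expect_equal(a$enrichment, -b$enrichment)
    expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  }
})

test_that("zero background mean is flagged and never passes", {
  fg <- setNames(rep(2L, 10), paste0("f", 1:10))
  bg <- setNames(rep(0L, 10), paste0("b", 1:10))
  r <- motif_enrichment(fg, bg)
  expect_true(is.na(r$enrichment))
  expect_false(is.na(r$enrichment_shrunk))
  df <- data.frame(matrix_id = "M", enrichment = NA_real_, p_adj = 1e-9,
                   genes_with_sites_fg = 10L, pct_with_sites = 100)
  expect_false(apply_pass_criteria(df)$passes)
})

test_that("BH adjustment matches its hand-derived values and is stable", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_fdr(0.042), 0.042)
  set.seed(63)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  ## adjusted values are monotone in raw values
  expect_true(all(diff(adjust_fdr(p)[order(p)]) >= 0))
})

test_that("pass criteria implement the four Table-1 rules", {
  df <- data.frame(
    matrix_id = c("ok", "few", "weak", "insig"),
    enrichment = c(2.1, 2.1, 0.9, 2.1),
    p_adj = c(0.001, 0.001, 1e-9, 0.01),
    genes_with_sites_fg = c(10L, 4L, 20L, 10L),
    pct_with_sites = c(50, 20, 100, 50))
  out <- apply_pass_criteria(df)
  expect_equal(out$passes, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("redundant matrices collapse to the smallest adjusted p", {
  df <- data.frame(
    matrix_id = c("V$NFKB_Q6_01", "V$NFKB_C", "V$ISRE_01"),
    p_raw = c(1e-9, 1e-6, 0.5),
    p_adj = c(1e-8, 1e-5, 0.5))
  out <- collapse_redundant(df)
  expect_setequal(out$matrix_id, c("V$NFKB_Q6_01", "V$ISRE_01"))
  ## singleton groups are identity
  solo <- collapse_redundant(df[3, ])
  expect_equal(solo$matrix_id, "V$ISRE_01")
  ## random grouping fixture against a per-group brute-force minimum
  set.seed(64)
  big <- data.frame(matrix_id = sprintf("M%02d", 1:40),
                    p_raw = runif(40), p_adj = runif(40))
  groups <- setNames(sample(letters[1:6], 40, TRUE), big$matrix_id)
  out <- collapse_redundant(big, groups)
  for (g in unique(groups)) {
    members <- big[groups[big$matrix_id] == g, ]
    best <- members$matrix_id[order(members$p_adj, members$p_raw,
                                    members$matrix_id)][1]
    expect_true(best %in% out$matrix_id)
  }
  expect_equal(nrow(out), length(unique(groups)))
})

test_that("regulated-gene selection applies fold, p and direction rules", {
  tab <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(1.01, 1.5, -1.2, 0.5),
    p_adj = c(0.005, 0.02, 0.001, 0.001))
  expect_equal(select_regulated(tab, direction = "up"), "a")
  expect_setequal(select_regulated(tab), c("a", "c"))
  expect_equal(select_regulated(tab, direction = "down"), "c")
  ## zero-noise synthetic table recovers the planted truth exactly
  de <- simulate_de_table(30, 20, 950, effect = 2, noise_sd = 0,
                          seed = 65)
  expect_setequal(select_regulated(de$table, direction = "up"),
                  de$truth$up)
  expect_setequal(select_regulated(de$table, direction = "down"),
                  de$truth$down)
  empty <- simulate_de_table(0, 0, 100, seed = 66)
  expect_length(select_regulated(empty$table), 0L)
})

test_that("strength/time cross-tab reproduces hand-computed percentages", {
  tab <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    time_window = rep(c("0-30", "30-60"), each = 3),
    log2fc = c(1.5, 2.5, 4.5, 1.5, 0.5, 4.1))
  sites <- list(ISRE = setNames(c(1L, 0L, 2L, 0L, 1L, 1L),
                                sprintf("g%d", 1:6)))
  ct <- strength_time_crosstab(tab, sites, fold_cuts = c(2, 16))
  ## 0-30, >2-fold: g1,g2,g3 -> 2/3 with sites
  expect_equal(ct$ISRE[ct$time_window == "0-30" & ct$fold_cut == 2],
               100 * 2 / 3)
  ## 30-60, >2-fold: g4,g6 -> 1/2
  expect_equal(ct$ISRE[ct$time_window == "30-60" & ct$fold_cut == 2], 50)
  ## >16-fold: log2fc > 4 strata
  expect_equal(ct$ISRE[ct$time_window == "0-30" & ct$fold_cut == 16], 100)
  ## all genes above cut carry the element -> 100%
  allcar <- strength_time_crosstab(
    data.frame(gene_id = "g3", time_window = "0-30", log2fc = 5),
    sites, fold_cuts = 2)
  expect_equal(allcar$ISRE, 100)
  ## one empty stratum -> one warning, NA percentage
  low <- tab[tab$time_window == "0-30" & tab$log2fc < 4, ]
  expect_warning(ct16 <- strength_time_crosstab(low, sites,
                                                fold_cuts = 16),
                 "no genes")
  expect_true(is.na(ct16$ISRE))
})

test_that("cooperativity recovers a perfect monotone and a planted trend", {
  genes <- sprintf("g%02d", 1:20)
  k <- setNames(0:19, genes)
  co <- cooperativity(k, setNames(as.numeric(0:19), genes))
  expect_equal(co$rho, 1)
  expect_lt(co$p, 1e-10)
  ## identical fold changes in all classes: flat medians, p = 1
  flat <- cooperativity(k, setNames(rep(2, 20), genes))
  expect_true(all(flat$medians == 2))
  expect_gte(flat$p, 0.99)
  ## additive model log2fc = 1 + 0.8 * count + noise
  set.seed(67)
  k2 <- setNames(rpois(100, 1.2), sprintf("h%03d", 1:100))
  f2 <- setNames(1 + 0.8 * k2 + rnorm(100, 0, 0.5), names(k2))
  co2 <- cooperativity(k2, f2)
  expect_gt(co2$rho, 0)
  expect_lt(co2$p, 0.01)
  expect_true(co2$medians[">1"] > co2$medians[["0"]])
})

test_that("per-gene normalization centres rows (and can z-score)", {
  expect_equal(per_gene_normalize(matrix(5, 3, 4)),
               matrix(0, 3, 4))
  expect_equal(per_gene_normalize(matrix(c(1, 2, 3), 1))[1, ],
               c(-1, 0, 1))
  set.seed(68)
  m <- matrix(rnorm(60), 10)
  expect_true(all(abs(rowSums(per_gene_normalize(m))) < 1e-9))
  z <- per_gene_normalize(m, "zscore")
  expect_equal(apply(z, 1, sd), rep(1, 10))
})
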