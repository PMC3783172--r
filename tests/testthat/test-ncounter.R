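## small literal run used by several blocks
toy_run <- function(neg = c(10, 10, 10), genes = c(t1 = 25, t2 = 12),
                    refs = c(r1 = 100, r2 = 200)) {
  counts <- cbind(s1 = c(genes, refs, neg))
  rownames(counts) <- c(names(genes), names(refs),
                        paste0("n", seq_along(neg)))
  roles <- setNames(c(rep("target", length(genes)),
                      rep("reference_candidate", length(refs)),
                      rep("negative_control", length(neg))),
                    rownames(counts))
  ncounter_run(counts, roles)
}

test_that("background threshold is mean + 2 SD of the negative controls", {
  r <- background_correct(toy_run())
  expect_equal(unname(r$bg_threshold), 10)      # zero-SD negatives
  expect_equal(r$corrected["t1", "s1"], 15)
  ## hand-computed two-negative case: mean 10, SD 2sqrt2, t = 15.657
  r2 <- background_correct(toy_run(neg = c(8, 12)))
  expect_equal(unname(r2$bg_threshold), 10 + 2 * sqrt(8),
               tolerance = 1e-12)
  expect_equal(r2$corrected["t2", "s1"], 0)     # 12 - 15.657, clamped
  expect_equal(r2$corrected["t1", "s1"], 25 - (10 + 2 * sqrt(8)))
  ## all-zero negatives leave the matrix unchanged
  r3 <- background_correct(toy_run(neg = c(0, 0, 0)))
  expect_equal(r3$corrected, r3$counts)
  expect_error(background_correct(toy_run(neg = 5)),
               "negative control")
})

test_that("stable-reference selection favours low-CV candidates", {
  ## constant candidate always wins
  counts <- rbind(t1 = c(50, 60, 70), flat = c(100, 100, 100),
                  wob = c(50, 150, 100), n1 = c(0, 0, 0), n2 = c(0, 0, 0))
  colnames(counts) <- paste0("s", 1:3)
  roles <- setNames(c("target", "reference_candidate",
                      "reference_candidate", "negative_control",
                      "negative_control"), rownames(counts))
  run <- ncounter_run(counts, roles)
  expect_equal(select_stable_references(run, 1), "flat")
  expect_setequal(select_stable_references(run, 2), c("flat", "wob"))
  expect_error(select_stable_references(run, 3), "exceeds")
  ## 3 low-noise vs 7 high-noise candidates, k = 3, 100 seeded replicates
  wins <- 0L
  for (s in 1:100) {
    sim <- simulate_ncounter_run(n_targets = 5, n_repressed = 0,
                                 n_refs = 10, cv = 0.05, scale_sd = 0,
                                 ref_noise_sd = c(0, 0, 0, rep(0.5, 7)),
                                 seed = 700 + s)
    sel <- select_stable_references(background_correct(sim$run), 3)
    if (setequal(sel, c("ref01", "ref02", "ref03"))) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("reference normalization equalises geomeans and is idempotent", {
  set.seed(81)
  counts <- matrix(rlnorm(60, log(200), 0.5), 10, 6,
                   dimnames = list(c(paste0("t", 1:4), paste0("r", 1:4),
                                     "n1", "n2"), paste0("s", 1:6)))
  counts[c("n1", "n2"), ] <- 0
  roles <- setNames(c(rep("target", 4), rep("reference_candidate", 4),
                      rep("negative_control", 2)), rownames(counts))
  run <- reference_normalize(background_correct(ncounter_run(counts, roles)),
                             paste0("r", 1:4))
  ## post-normalization per-sample reference geomeans are all equal
  g <- exp(colMeans(log(run$normalized[paste0("r", 1:4), ])))
  expect_true(all(abs(g - mean(g)) < 1e-9))
  ## idempotence: renormalizing changes nothing, scales are 1
  run2 <- reference_normalize(
    ncounter_run(run$normalized, roles) |> background_correct(),
    paste0("r", 1:4))
  ## background threshold of the renormalized run is 0 (zero negatives)
  expect_true(all(abs(run2$scale - 1) < 1e-9))
  expect_equal(run2$normalized, run$normalized, tolerance = 1e-9)
  ## sample B = 2 x sample A globally: scale_B/scale_A = 1/2 and the
  ## normalized columns coincide
  two <- counts[, c("s1", "s1")]
  colnames(two) <- c("A", "B")
  two[, "B"] <- 2 * two[, "B"]
  ab <- reference_normalize(
    background_correct(ncounter_run(two, roles)), paste0("r", 1:4))
  expect_equal(unname(ab$scale["B"] / ab$scale["A"]), 0.5,
               tolerance = 1e-12)
  expect_equal(ab$normalized[, "B"], ab$normalized[, "A"],
               tolerance = 1e-12)
  ## rescaling one sample of a run leaves normalized values invariant up
  ## to the common anchor constant
  doubled <- counts
  doubled[, "s2"] <- 2 * doubled[, "s2"]
  rund <- reference_normalize(
    background_correct(ncounter_run(doubled, roles)), paste0("r", 1:4))
  nz <- run$normalized > 0
  ratio <- rund$normalized[nz] / run$normalized[nz]
  expect_lt(diff(range(ratio)), 1e-9)
  ## a reference at zero in any sample is a named error
  bad <- counts; bad["r2", "s3"] <- 0
  expect_error(reference_normalize(
    background_correct(ncounter_run(bad, roles)), paste0("r", 1:4)),
    "r2.*s3")
})

test_that("repression calls use the fractional-reduction rule", {
  mat <- rbind(a = c(100, 100, 75, 75), b = c(100, 100, 85, 85),
               z = c(0, 0, 10, 10))
  colnames(mat) <- c("m1", "m2", "i1", "i2")
  calls <- suppressWarnings(
    call_repression(mat, treated = c("i1", "i2"), mock = c("m1", "m2")))
  expect_true(calls[["a"]])        # 25% reduction
  expect_false(calls[["b"]])       # 15% reduction
  expect_true(is.na(calls[["z"]])) # zero mock mean
  expect_warning(
    call_repression(mat, c("i1", "i2"), c("m1", "m2")), "undefined")
})

test_that("planted repression is recovered with realistic noise", {
  called <- miscalled <- numeric(100)
  for (s in 1:100) {
    sim <- simulate_ncounter_run(n_targets = 40, n_repressed = 20,
                                 repression = 0.4, cv = 0.1,
                                 seed = 900 + s)
    res <- run_ncounter(pipeline_config(), run = sim$run)
    nulls <- setdiff(names(res$calls), sim$truth$repressed)
    called[s] <- sum(res$calls[sim$truth$repressed], na.rm = TRUE)
    miscalled[s] <- sum(res$calls[nulls], na.rm = TRUE)
  }
  expect_gte(mean(called), 18)
  expect_lte(mean(miscalled), 1)
})

test_that("the exact Fisher test matches enumeration and its invariances", {
  ## the STAT1 dependence worked example prints 0.0019
  ft <- fisher_exact(matrix(c(11, 8, 2, 19), 2, byrow = TRUE))
  expect_equal(round(ft$p.value, 4), 0.0019)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  ## random tables vs the independent implementation in stats
  set.seed(83)
  for (rep in 1:60) {
    tab <- matrix(rpois(4, sample(1:10, 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab)$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    ## invariant under transposition and simultaneous row+col swap
    expect_equal(fisher_exact(t(tab))$p.value,
                 fisher_exact(tab)$p.value, tolerance = 1e-12)
    expect_equal(fisher_exact(tab[2:1, 2:1])$p.value,
                 fisher_exact(tab)$p.value, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("zero-noise simulated runs recover scales and repression exactly", {
  sim <- simulate_ncounter_run(n_targets = 10, n_repressed = 5,
                               repression = 0.4, cv = 0, bg_mean = 10,
                               bg_sd = 0, scale_sd = 0.3, seed = 91)
  run <- normalize_ncounter(sim$run, k = 7)
  ## planted per-sample scale factors are removed
  rel <- run$scale * sim$truth$scale
  expect_true(all(abs(rel / mean(rel) - 1) < 1e-6))
  ## planted repression fractions recovered exactly
  m <- rowMeans(run$normalized[sim$truth$repressed, sim$truth$mock])
  tr <- rowMeans(run$normalized[sim$truth$repressed, sim$truth$treated])
  expect_equal(unname(1 - tr / m), rep(0.4, 5), tolerance = 1e-9)
})
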