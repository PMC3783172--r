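## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (and stats::dwilcox) so that each check is a
## genuine dual route.

## term-by-term evaluation of the matrix similarity score
mss_oracle <- function(p, word) {
  b <- strsplit(word, "")[[1L]]
  L <- nrow(p$frequencies)
  cur <- mn <- mx <- 0
  for (i in seq_len(L)) {
    f <- p$frequencies[i, ]
    nz <- f > 0
    info <- sum(f[nz] * log(4 * f[nz]))
    cur <- cur + info * f[[b[i]]]
    mn <- mn + info * min(f)
    mx <- mx + info * max(f)
  }
  if (mx == mn) return(1)
  (cur - mn) / (mx - mn)
}

## exact null distribution of the Mann-Whitney U statistic by the
## largest-observation recurrence N(u;n,m) = N(u-m;n-1,m) + N(u;n,m-1)
.u_memo <- new.env(parent = emptyenv())
u_counts <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.u_memo[[key]])) return(.u_memo[[key]])
  res <- if (n == 0L || m == 0L) 1 else {
    a <- u_counts(n - 1L, m)
    b <- u_counts(n, m - 1L)
    v <- numeric(n * m + 1L)
    v[(m + 1L):(m + length(a))] <- a
    v[seq_along(b)] <- v[seq_along(b)] + b
    v
  }
  .u_memo[[key]] <- res
  res
}

## two-sided exact p for observed U (doubled smaller tail, capped at 1)
exact_mww_p <- function(u, n, m) {
  cnt <- u_counts(n, m)
  tot <- sum(cnt)
  lo <- sum(cnt[seq_len(u + 1L)]) / tot
  hi <- sum(cnt[(u + 1L):length(cnt)]) / tot
  min(1, 2 * min(lo, hi))
}

## construct untied samples (x of size n, y of size m) achieving a given
## U = number of (x, y) pairs with x > y
samples_with_u <- function(u, n, m) {
  y <- 10 * seq_len(m)
  beats <- integer(n)
  left <- u
  for (i in seq_len(n)) {
    beats[i] <- min(m, left)
    left <- left - beats[i]
  }
  stopifnot(left == 0L)
  x <- 10 * beats + 5 + seq_len(n) * 1e-3
  list(x = x, y = y)
}

## a tiny sharp PWM for planted-match tests: consensus GATTACA
toy_pwm <- function(id = "TOY") {
  counts <- matrix(2, 7, 4)
  cons <- c("G", "A", "T", "T", "A", "C", "A")
  for (i in seq_along(cons))
    counts[i, match(cons[i], c("A", "C", "G", "T"))] <- 94
  pwm(counts, matrix_id = id, factor_name = paste0("V$", id))
}

## random PWM with a given length (moderate sharpness)
random_pwm <- function(L, id = "RND", sharp = 0.7) {
  counts <- matrix(0, L, 4)
  for (i in seq_len(L)) {
    counts[i, ] <- round(100 * (1 - sharp) / 3)
    counts[i, sample.int(4L, 1L)] <- round(100 * sharp)
  }
  pwm(counts, matrix_id = id)
}

random_word <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
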