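# Independent oracle implementations used to cross-check the package's
# optimized code paths, plus small-world builders. Oracles are written as
# plain dense loops and share no code with the implementation under test.

# --- dense ICE fixed-point oracle -------------------------------------------

# Plain dense iterative correction: mask given, weights iterated on the
# full symmetric dense matrix until the balanced marginals are flat to
# `tol`, then rescaled to mean-1 marginals.
oracle_ice_dense <- function(dense_sym, mask, tol = 1e-10, max_iter = 5000L) {
  n <- nrow(dense_sym)
  w <- ifelse(mask, 0, 1)
  for (it in seq_len(max_iter)) {
    bm <- w * as.numeric(dense_sym %*% w)
    mu <- mean(bm[!mask])
    cv <- stats::sd(bm[!mask]) / mu
    if (is.finite(cv) && cv < tol) break
    adj <- bm / mu
    adj[mask | adj == 0] <- 1
    w <- w / adj
  }
  bm <- w * as.numeric(dense_sym %*% w)
  w <- w / sqrt(mean(bm[!mask]))
  w[mask] <- NA_real_
  w
}

dense_symmetric_counts <- function(m) {
  x <- as.matrix(m$counts)
  x + t(x) - diag(diag(x))
}

# --- dense pile-up oracle ----------------------------------------------------

# Direct per-feature implementation: dense obs/exp window, per-pixel
# area-weighted average computed with explicit loops over source bins.
oracle_pileup <- function(m, features, cfg, expected) {
  res <- m$genome$resolution
  n <- m$genome$n_bins
  w <- m$weights
  dense <- dense_symmetric_counts(m)
  dense <- dense * outer(ifelse(is.na(w), 0, w), ifelse(is.na(w), 0, w))
  ts <- cfg$rescale_size
  acc <- matrix(0, ts, ts); cnt <- matrix(0L, ts, ts)
  for (f in seq_len(nrow(features))) {
    L <- features$end[f] - features$start[f]
    ws <- features$start[f] - cfg$flank * L
    we <- features$end[f] + cfg$flank * L
    if (ws < 0 || we > m$genome$length) next
    b1 <- floor(ws / res) + 1L
    b2 <- floor((we - 1) / res) + 1L
    nb <- b2 - b1 + 1L
    if (ts > 4L * nb) next
    win <- matrix(NA_real_, nb, nb)
    for (a in seq_len(nb)) {
      for (b in seq_len(nb)) {
        i <- b1 + a - 1L; j <- b1 + b - 1L
        d <- abs(i - j)
        if (d < cfg$ignore_diags) next
        if (is.na(w[i]) || is.na(w[j])) next
        v <- dense[i, j]
        if (cfg$use_obs_exp) {
          ev <- expected$expected[d + 1L]
          if (is.na(ev)) next
          v <- v / ev
        }
        win[a, b] <- v
      }
    }
    step <- nb / ts
    covered <- function(k) {
      max(1L, floor((k - 1) * step) + 1L):min(nb, ceiling(k * step))
    }
    for (a in seq_len(ts)) {
      for (b in seq_len(ts)) {
        num <- 0; den <- 0
        for (sa in covered(a)) {
          wa <- min(a * step, sa) - max((a - 1) * step, sa - 1)
          if (wa <= 1e-12) next
          for (sb in covered(b)) {
            wb <- min(b * step, sb) - max((b - 1) * step, sb - 1)
            if (wb <= 1e-12) next
            if (is.na(win[sa, sb])) next
            num <- num + wa * wb * win[sa, sb]
            den <- den + wa * wb
          }
        }
        if (den > 1e-12) {
          acc[a, b] <- acc[a, b] + num / den
          cnt[a, b] <- cnt[a, b] + 1L
        }
      }
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

# --- dense SCC oracle --------------------------------------------------------

oracle_scc <- function(m1, m2, h, max_dist) {
  sm <- function(mat) {
    k <- rep(1, 2 * h + 1)
    pad <- function(v) as.numeric(stats::filter(v, k, sides = 2))
    n <- nrow(mat)
    counts <- as.numeric(stats::filter(rep(1, n), k, sides = 2))
    counts[is.na(counts)] <- 0
    rows <- t(apply(mat, 1, function(v) {
      s <- pad(v)
      # truncated window: recompute edge sums explicitly
      for (i in seq_len(n)) {
        if (is.na(s[i])) s[i] <- sum(v[max(1, i - h):min(n, i + h)])
      }
      s / (pmin(n, seq_len(n) + h) - pmax(1, seq_len(n) - h) + 1)
    }))
    cols <- apply(rows, 2, function(v) {
      s <- pad(v)
      for (i in seq_len(n)) {
        if (is.na(s[i])) s[i] <- sum(v[max(1, i - h):min(n, i + h)])
      }
      s / (pmin(n, seq_len(n) + h) - pmax(1, seq_len(n) - h) + 1)
    })
    cols
  }
  a <- sm(dense_symmetric_counts(m1))
  b <- sm(dense_symmetric_counts(m2))
  n <- nrow(a)
  dmax <- min(n - 1L, floor(max_dist / m1$genome$resolution))
  num <- 0; den <- 0
  for (d in 1:dmax) {
    idx <- seq_len(n - d)
    x <- a[cbind(idx, idx + d)]; y <- b[cbind(idx, idx + d)]
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    wgt <- length(x) * sqrt(stats::var(rank(signif(x, 9)) / length(x)) *
                            stats::var(rank(signif(y, 9)) / length(y)))
    num <- num + wgt * stats::cor(x, y)
    den <- den + wgt
  }
  num / den
}

# --- brute-force overlap counting -------------------------------------------

oracle_count_overlaps <- function(A, B, f) {
  if (!nrow(A) || !nrow(B)) return(0L)
  # merge B into a union of disjoint intervals
  o <- order(B$start)
  bs <- B$start[o]; be <- B$end[o]
  ms <- bs[1]; me <- be[1]; us <- c(); ue <- c()
  for (k in seq_along(bs)[-1]) {
    if (bs[k] <= me) me <- max(me, be[k]) else {
      us <- c(us, ms); ue <- c(ue, me); ms <- bs[k]; me <- be[k]
    }
  }
  us <- c(us, ms); ue <- c(ue, me)
  cnt <- 0L
  for (a in seq_len(nrow(A))) {
    ov <- 0
    for (u in seq_along(us)) {
      ov <- ov + max(0, min(A$end[a], ue[u]) - max(A$start[a], us[u]))
    }
    if (ov >= f * (A$end[a] - A$start[a]) - 1e-9) cnt <- cnt + 1L
  }
  cnt
}

with_fixed_seed <- function(seed, code) withr::with_seed(seed, code)

# --- world builders ----------------------------------------------------------

# Small pure-decay truth (no planted features).
pure_decay_truth <- function(seed, genome_length = 100000, depth = 4e5,
                             resolution = 100) {
  empty_chins <- data.frame(center = numeric(0), extent = numeric(0),
                            enrichment = numeric(0))
  empty_pairs <- data.frame(i = integer(0), j = integer(0),
                            enrichment = numeric(0), sd = numeric(0))
  no_ops <- data.frame(start = 1000, end = 3000, strand = "+", id = "op_1",
                       activity = 0)
  cfg <- sim_config(genome_length = genome_length, resolution = resolution,
                    base_depth = depth, operons = no_ops,
                    opcids = data.frame(start = numeric(0), end = numeric(0),
                                        tss = numeric(0), tes = numeric(0),
                                        domain_enrichment = numeric(0),
                                        corner_strength = numeric(0),
                                        corner_sd = numeric(0)),
                    chins = empty_chins, chin_pairs = empty_pairs)
  make_truth(cfg, seed = seed)
}

# Mark a bias-free synthetic matrix as balanced with unit weights (the
# exact balance for a map simulated without per-bin biases). Used where a
# planted enrichment must be read back undistorted; ICE itself is
# exercised by its own contract tests.
with_unit_weights <- function(m) {
  m$weights <- rep(1, m$genome$n_bins)
  m$cache <- new.env(parent = emptyenv())
  m
}

# Contact matrix built directly from a dense symmetric matrix of values
# (taken as exact counts), unit weights.
matrix_from_dense <- function(genome, dense) {
  idx <- which(upper.tri(dense, diag = TRUE) & dense != 0, arr.ind = TRUE)
  m <- contact_matrix(genome, idx[, 1], idx[, 2], dense[idx])
  with_unit_weights(m)
}

# Uniform expected profile (E(d) = value for every allowed diagonal).
flat_expected <- function(n_bins, value = 1, ignore_diags = 0L,
                          resolution = 100) {
  e <- data.frame(dist_bins = 0:(n_bins - 1L),
                  expected = rep(value, n_bins),
                  expected_smoothed = rep(value, n_bins),
                  valid_pairs = rep(n_bins, n_bins))
  e$expected[e$dist_bins < ignore_diags] <- NA_real_
  attr(e, "ignore_diags") <- as.integer(ignore_diags)
  attr(e, "resolution") <- resolution
  class(e) <- c("expected_profile", class(e))
  e
}
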