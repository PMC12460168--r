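# Local rescaled average contact maps ("pile-ups") and 1D meta-profiles.
#
# Rescaling uses area-weighted block averaging: a sparse projection matrix
# maps source bins onto target pixels with fractional-coverage weights, so
# the operation is mass-preserving and deterministic for both down- and
# up-sampling. Undefined (masked or ignored-diagonal) pixels are excluded
# from every average rather than treated as zero.

#' Pile-up configuration
#'
#' @param rescale_size Odd target grid size in pixels (default 401).
#' @param flank Flank width as a multiple of feature length (default 1).
#' @param ignore_diags Diagonals (in matrix bins) excluded near the main
#'   diagonal (default 2); the corresponding grid pixels are undefined.
#' @param use_obs_exp Divide balanced values by the distance-decay expected
#'   (default TRUE).
#' @return A list of class `pileup_config`.
#' @export
pileup_config <- function(rescale_size = 401L, flank = 1, ignore_diags = 2L,
                          use_obs_exp = TRUE) {
  rescale_size <- as.integer(rescale_size)
  if (rescale_size < 3L || rescale_size %% 2L == 0L) {
    stop("rescale_size must be odd and >= 3")
  }
  if (flank < 0) stop("flank must be >= 0")
  structure(list(rescale_size = rescale_size, flank = flank,
                 ignore_diags = as.integer(ignore_diags),
                 use_obs_exp = isTRUE(use_obs_exp)),
            class = "pileup_config")
}

# T x S area-weighted projection: row k averages the source bins covered by
# target pixel k; rows sum to 1.
projection_matrix <- function(n_source, n_target) {
  step <- n_source / n_target
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_len(n_target)) {
    lo <- (k - 1) * step; hi <- k * step
    b0 <- floor(lo + 1e-12); b1 <- ceiling(hi - 1e-12)
    bins <- (b0 + 1):b1
    wt <- pmin(hi, bins) - pmax(lo, bins - 1)
    keep <- wt > 1e-12
    i <- c(i, rep.int(k, sum(keep))); j <- c(j, bins[keep]); x <- c(x, wt[keep])
  }
  p <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_target, n_source))
  p / Matrix::rowSums(p)
}

# NA-aware projection of a square matrix onto a T x T grid.
project_grid <- function(win, proj) {
  def <- !is.na(win)
  w0 <- win; w0[!def] <- 0
  num <- as.matrix(proj %*% w0 %*% Matrix::t(proj))
  den <- as.matrix(proj %*% (def + 0) %*% Matrix::t(proj))
  out <- num / den
  out[den <= 1e-12] <- NA_real_
  out
}

# Dense obs/exp (or balanced) window on bins [b1, b2], NA where undefined.
oe_window <- function(m, expected, b1, b2, ignore_diags, use_obs_exp) {
  blk <- balanced_block(m, b1:b2, b1:b2)
  nb <- b2 - b1 + 1L
  dmat <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  if (use_obs_exp) {
    ev <- expected$expected[dmat + 1L]
    blk <- blk / ev
  }
  blk[dmat < ignore_diags] <- NA_real_
  blk
}

#' Local rescaled average contact map over a feature set
#'
#' For each feature of length L, the on-diagonal window
#' `[start - flank*L, end + flank*L)` is extracted as balanced (or
#' balanced/expected) values, area-weighted block-averaged onto a
#' `rescale_size x rescale_size` grid, and the grids are averaged pixelwise
#' ignoring undefined pixels. Features whose window leaves the genome, or
#' whose window is narrower than `rescale_size / 4` bins, are dropped and
#' counted.
#'
#' @param m A balanced `contact_matrix`.
#' @param features A `genomic_intervals` table.
#' @param cfg A [pileup_config()].
#' @param expected An [expected_by_distance()] profile computed with the
#'   same `ignore_diags` (required when `cfg$use_obs_exp`).
#' @return A list of class `pileup_result`: `grid` (mean values, NA where
#'   never defined), `n_contrib` (per-pixel contribution counts),
#'   `n_features` used and `n_dropped`.
#' @export
local_rescaled_pileup <- function(m, features, cfg = pileup_config(),
                                  expected = NULL) {
  if (!is_balanced(m)) stop("matrix is not balanced; run ice_balance() first")
  if (!nrow(features)) stop("empty feature list")
  if (cfg$use_obs_exp) {
    if (is.null(expected)) stop("expected profile required for obs/exp pile-up")
    if (attr(expected, "ignore_diags") != cfg$ignore_diags) {
      stop("expected profile computed with different ignore_diags")
    }
  }
  res <- m$genome$resolution
  n <- m$genome$n_bins
  ts <- cfg$rescale_size
  acc <- matrix(0, ts, ts); cnt <- matrix(0L, ts, ts)
  dropped <- 0L
  for (f in seq_len(nrow(features))) {
    L <- features$end[f] - features$start[f]
    ws <- features$start[f] - cfg$flank * L
    we <- features$end[f] + cfg$flank * L
    if (ws < 0 || we > m$genome$length) { dropped <- dropped + 1L; next }
    b1 <- floor(ws / res) + 1L
    b2 <- floor((we - 1) / res) + 1L
    nb <- b2 - b1 + 1L
    if (ts > 4L * nb) {
      warning(sprintf("feature %s window (%d bins) too small for rescale_size %d; dropped",
                      features$id[f], nb, ts))
      dropped <- dropped + 1L
      next
    }
    win <- oe_window(m, expected, b1, b2, cfg$ignore_diags, cfg$use_obs_exp)
    grid <- project_grid(win, projection_matrix(nb, ts))
    def <- !is.na(grid)
    acc[def] <- acc[def] + grid[def]
    cnt <- cnt + def
  }
  used <- nrow(features) - dropped
  if (used == 0L) stop("all features dropped")
  out <- acc / cnt
  out[cnt == 0L] <- NA_real_
  structure(list(grid = out, n_contrib = cnt, n_features = used,
                 n_dropped = dropped, config = cfg),
            class = "pileup_result")
}

#' Write a pile-up grid as TSV plus JSON metadata
#' @param p A `pileup_result`.
#' @param path Output TSV path (grid only); metadata goes to `<path>.json`.
#' @export
write_pileup <- function(p, path) {
  utils::write.table(p$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(rescale_size = p$config$rescale_size, flank = p$config$flank,
         ignore_diags = p$config$ignore_diags, n_features = p$n_features,
         n_dropped = p$n_dropped),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- 1D signal tracks and meta-profiles -------------------------------------

#' Construct a per-bin signal track
#'
#' @param values Finite non-negative numeric vector (one value per bin).
#' @param bin_size Bin width in bp.
#' @return A list of class `signal_track`.
#' @export
signal_track <- function(values, bin_size) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("signal track values must be finite and non-negative")
  }
  structure(list(values = values, bin_size = as.numeric(bin_size)),
            class = "signal_track")
}

#' Read / write a bedGraph signal track
#'
#' Uses `rtracklayer` for parsing/serialization. The track must tile the
#' genome in constant-width bins (the format this package writes).
#'
#' @param path bedGraph path.
#' @param genome A `genome_spec`.
#' @return `read_bedgraph` returns a `signal_track`.
#' @rdname bedgraph_io
#' @export
read_bedgraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  st <- GenomicRanges::start(gr) - 1L
  en <- GenomicRanges::end(gr)
  widths <- en - st
  bs <- widths[1]
  n <- as.integer(ceiling(genome$length / bs))
  vals <- numeric(n)
  bins <- st %/% bs + 1L
  vals[bins] <- gr$score
  signal_track(vals, bs)
}

#' @param track A `signal_track`.
#' @param chrom Chromosome name to write.
#' @rdname bedgraph_io
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  n <- length(track$values)
  starts <- (seq_len(n) - 1L) * track$bin_size
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = starts + track$bin_size),
    score = track$values
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Meta-profile configuration
#'
#' @param flank Flank width in bp kept at fixed scale (500 or 1000 are the
#'   usual choices; default 500).
#' @param body_bins Number of positions the feature body is rescaled to
#'   (default 50).
#' @param flank_bins Number of positions per flank (default
#'   `flank / track bin size`, fixed at profile time).
#' @param n_boot Bootstrap replicates for the standard error (default 100).
#' @param anchored If TRUE, the body is not rescaled; profiles are anchored
#'   at the feature start over `body_bins` native bins instead.
#' @return A list of class `profile_config`.
#' @export
profile_config <- function(flank = 500, body_bins = 50L, flank_bins = NULL,
                           n_boot = 100L, anchored = FALSE) {
  stopifnot(flank >= 0, body_bins >= 1)
  structure(list(flank = flank, body_bins = as.integer(body_bins),
                 flank_bins = flank_bins, n_boot = as.integer(n_boot),
                 anchored = isTRUE(anchored)),
            class = "profile_config")
}

# Area-weighted mean of track values over [from, to) bp, in nbins bins.
resample_track <- function(track, from, to, nbins) {
  bs <- track$bin_size
  n <- length(track$values)
  out <- numeric(nbins)
  step <- (to - from) / nbins
  for (k in seq_len(nbins)) {
    lo <- from + (k - 1) * step; hi <- from + k * step
    b0 <- floor(lo / bs + 1e-9); b1 <- ceiling(hi / bs - 1e-9)
    bins <- (b0 + 1):b1
    wt <- pmin(hi, bins * bs) - pmax(lo, (bins - 1) * bs)
    ok <- bins >= 1 & bins <= n & wt > 0
    out[k] <- if (any(ok)) sum(track$values[bins[ok]] * wt[ok]) / sum(wt[ok]) else NA_real_
  }
  out
}

#' Average 1D signal profile around oriented features
#'
#' Each feature body is rescaled to `body_bins` positions; flanks of
#' `flank` bp are kept at a fixed bp scale. Profiles of minus-strand
#' features are reversed so all run 5'->3'. Positionwise mean and a
#' feature-resampling bootstrap standard error are returned.
#'
#' @param track A [signal_track()].
#' @param features Oriented `genomic_intervals` (strand `.` treated as `+`).
#' @param cfg A [profile_config()].
#' @param genome A `genome_spec` (bounds; features whose padded window
#'   leaves the genome are dropped).
#' @param seed RNG seed for the bootstrap (default 1).
#' @return data.frame with `position` (bins; flank positions negative /
#'   beyond body), `mean`, `se`, `n`, plus attribute `matrix` holding the
#'   per-feature profile matrix.
#' @export
signal_profile_around <- function(track, features, cfg = profile_config(),
                                  genome, seed = 1L) {
  stopifnot(inherits(track, "signal_track"))
  if (!nrow(features)) stop("empty feature list")
  if (any(features$end - features$start > genome$length / 2)) {
    stop("feature longer than half the genome")
  }
  fb <- if (is.null(cfg$flank_bins)) as.integer(round(cfg$flank / track$bin_size))
        else as.integer(cfg$flank_bins)
  bb <- cfg$body_bins
  total <- fb + bb + fb
  rows <- list()
  for (f in seq_len(nrow(features))) {
    s <- features$start[f]; e <- features$end[f]
    if (s - cfg$flank < 0 || e + cfg$flank > genome$length) next
    left <- if (fb > 0) resample_track(track, s - cfg$flank, s, fb) else numeric(0)
    body <- if (cfg$anchored) {
      resample_track(track, s, s + bb * track$bin_size, bb)
    } else {
      resample_track(track, s, e, bb)
    }
    right <- if (fb > 0) resample_track(track, e, e + cfg$flank, fb) else numeric(0)
    prof <- c(left, body, right)
    if (identical(features$strand[f], "-")) prof <- rev(prof)
    rows[[length(rows) + 1L]] <- prof
  }
  if (!length(rows)) stop("all features dropped (flank beyond genome bounds)")
  mat <- do.call(rbind, rows)
  mu <- colMeans(mat, na.rm = TRUE)
  nfeat <- nrow(mat)
  se <- rep(NA_real_, total)
  if (nfeat > 1 && cfg$n_boot > 0) {
    boots <- matrix(NA_real_, cfg$n_boot, total)
    with_seed(seed, {
      for (b in seq_len(cfg$n_boot)) {
        idx <- sample.int(nfeat, nfeat, replace = TRUE)
        boots[b, ] <- colMeans(mat[idx, , drop = FALSE], na.rm = TRUE)
      }
    })
    se <- apply(boots, 2, stats::sd)
  }
  pos <- c(if (fb > 0) -(fb:1) else integer(0), seq_len(bb),
           if (fb > 0) bb + seq_len(fb) else integer(0))
  out <- data.frame(position = pos, mean = mu, se = se, n = nfeat)
  attr(out, "matrix") <- mat
  out
}
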