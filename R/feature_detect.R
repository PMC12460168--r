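# Detection of the three structure classes on observed/expected maps:
# chromosomal hairpins (CHINs, anti-diagonal ridges), hairpin domains
# (CHIDs, clusters of overlapping hairpins) and operon-sized contact
# domains (OPCIDs, on-diagonal squares), plus inter-hairpin contact
# scoring. Detection is template matching: Pearson correlation between the
# local log obs/exp window and an anti-diagonal ridge template, followed
# by non-maximum suppression and ridge-following extent estimation.
# Everything is deterministic: no randomness enters detection.

#' Detection configuration
#'
#' @param kernel_halfwidth Half-width of the square scoring window in bins
#'   (default 12).
#' @param score_threshold Minimum kernel correlation for a call
#'   (default 0.3).
#' @param min_extent Minimum stem genomic span in bp for an emitted call
#'   (default 300).
#' @param merge_gap Non-maximum-suppression radius in bp: among candidate
#'   centers closer than this, only the best-scoring survives
#'   (default 1000).
#' @param stem_width Template ridge half-width in bins: pixels with
#'   `|i + j - 2c| <= stem_width` belong to the ridge (default 2, matching
#'   the typical stem cross-section).
#' @param max_extent Longest stem span considered in bp (default 8000).
#' @param ridge_frac Extent estimation stops where the smoothed ridge
#'   obs/exp drops below `1 + ridge_frac * (peak - 1)` (default 0.5).
#' @param log_eps Pseudo-value added before taking logs of obs/exp
#'   (default 0.1; avoids -Inf on empty pixels).
#' @param chid_min_members Minimum hairpins per CHID (default 2).
#' @param chid_max_gap Maximum gap in bp between member footprints
#'   (default 1000).
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(kernel_halfwidth = 12L, score_threshold = 0.3,
                          min_extent = 300, merge_gap = 1000,
                          stem_width = 2, max_extent = 8000,
                          ridge_frac = 0.5, log_eps = 0.1,
                          chid_min_members = 2L, chid_max_gap = 1000) {
  stopifnot(score_threshold > 0, score_threshold < 1,
            merge_gap >= 0, chid_max_gap >= 0, kernel_halfwidth >= 2)
  structure(list(kernel_halfwidth = as.integer(kernel_halfwidth),
                 score_threshold = score_threshold, min_extent = min_extent,
                 merge_gap = merge_gap, stem_width = stem_width,
                 max_extent = max_extent, ridge_frac = ridge_frac,
                 log_eps = log_eps,
                 chid_min_members = as.integer(chid_min_members),
                 chid_max_gap = chid_max_gap),
            class = "detect_config")
}

# Band view of the obs/exp map: oe[i, d+1] = balanced(i, i+d) / E(d) for
# d = 0..max_sep; NA where either bin is masked or E undefined.
oe_band <- function(m, expected, max_sep) {
  n <- m$genome$n_bins
  max_sep <- min(max_sep, n - 1L)
  w <- m$weights
  band <- matrix(0, n, max_sep + 1L)
  tr <- as_triplets(m)
  d <- tr$j - tr$i
  keep <- d <= max_sep
  bi <- tr$i[keep]; bd <- d[keep]
  bx <- tr$x[keep] * w[bi] * w[tr$j[keep]]
  band[cbind(bi, bd + 1L)] <- bx
  ev <- expected$expected[1:(max_sep + 1L)]
  band <- sweep(band, 2, ev, "/")
  masked <- is.na(w)
  for (dd in 0:max_sep) {
    rows <- seq_len(n - dd)
    bad <- masked[rows] | masked[rows + dd]
    band[rows[bad], dd + 1L] <- NA_real_
    if (dd < n) band[seq.int(n - dd + 1L, length.out = dd), dd + 1L] <- NA_real_
  }
  band
}

# Ridge-template extents (bins) used by the scorer: roughly geometric
# between the shortest resolvable stem and the window span.
template_extents <- function(ignore, hw) {
  lo <- max(ignore + 2L, 4L)
  hi <- 2L * hw
  if (hi <= lo) return(hi)
  unique(round(exp(seq(log(lo), log(hi), length.out = 7L))))
}

# Vectorized hairpin scoring. For every candidate apex bin c, the square
# window (i, j) = (c + u, c + v), |u|,|v| <= hw, j - i >= ignore is
# correlated against a bank of binary anti-diagonal ridge templates
# (1 on |i + j - 2c| <= stem_width and separation <= extent, 0 elsewhere),
# one per candidate extent; the best template wins. Because templates are
# binary and nested in extent, all Pearson terms reduce to cumulative sums
# that are accumulated in O(window area) vector passes over the band.
# Returns per-center best score (NA where the window leaves the genome or
# is >50% masked, or degenerate) and the best template extent in bins.
chin_score_scan <- function(band, n, hw, ignore, stem_width, log_eps,
                            extents = template_extents(ignore, hw)) {
  centers <- (hw + 1L):(n - hw)
  nc <- length(centers)
  lb <- log(band + log_eps)
  N <- numeric(nc); Sx <- numeric(nc); Sxx <- numeric(nc)
  n_px <- 0L
  for (u in (-hw):(hw - ignore)) {
    dcols <- ignore:(hw - u)
    mch <- lb[centers + u, dcols + 1L, drop = FALSE]
    def <- !is.na(mch)
    mch[!def] <- 0
    N <- N + rowSums(def)
    Sx <- Sx + rowSums(mch)
    Sxx <- Sxx + rowSums(mch^2)
    n_px <- n_px + length(dcols)
  }
  dmax <- 2L * hw
  # ridge cumulative sums over separation
  RSt <- matrix(0, nc, length(extents))
  RSxt <- matrix(0, nc, length(extents))
  cSt <- numeric(nc); cSxt <- numeric(nc)
  eidx <- 1L
  for (d in ignore:dmax) {
    us <- ceiling((-d - stem_width) / 2):floor((-d + stem_width) / 2)
    us <- us[us >= -hw & us <= hw - d]
    for (u in us) {
      v <- lb[centers + u, d + 1L]
      def <- !is.na(v)
      v[!def] <- 0
      cSt <- cSt + def
      cSxt <- cSxt + v
    }
    while (eidx <= length(extents) && extents[eidx] == d) {
      RSt[, eidx] <- cSt; RSxt[, eidx] <- cSxt
      eidx <- eidx + 1L
    }
    if (eidx <= length(extents) && d == dmax) {
      # remaining templates saturate at the window edge
      for (k in eidx:length(extents)) { RSt[, k] <- cSt; RSxt[, k] <- cSxt }
    }
  }
  best <- rep(NA_real_, nc); best_ext <- rep(NA_real_, nc)
  ok_win <- N >= n_px / 2 & N > 3
  for (k in seq_along(extents)) {
    St <- RSt[, k]; Sxt <- RSxt[, k]
    num <- Sxt - Sx * St / N
    varx <- Sxx - Sx^2 / N
    vart <- St - St^2 / N
    r <- rep(NA_real_, nc)
    good <- ok_win & varx > 1e-12 & vart > 1e-12
    r[good] <- num[good] / sqrt(varx[good] * vart[good])
    upd <- !is.na(r) & (is.na(best) | r > best)
    best[upd] <- r[upd]
    best_ext[upd] <- extents[k]
  }
  list(centers = centers, score = best, best_extent = best_ext)
}

#' Hairpin kernel score at one center
#'
#' Pearson correlation between the local `log(obs/exp + log_eps)` window
#' centred on the main diagonal at `center` and a bank of anti-diagonal
#' ridge templates (1 on `|i + j - 2c| <= stem_width` up to a candidate
#' stem extent, 0 elsewhere); the best-matching template's correlation is
#' returned. Undefined (`NA`) when more than half of the window pixels are
#' masked, when the window leaves the genome or when the window has zero
#' variance.
#'
#' @param m A balanced `contact_matrix`.
#' @param expected An [expected_by_distance()] profile.
#' @param center Center position in bp (the hairpin apex).
#' @param cfg A [detect_config()].
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
hairpin_kernel_score <- function(m, expected, center, cfg = detect_config()) {
  res <- m$genome$resolution
  ignore <- attr(expected, "ignore_diags")
  hw <- cfg$kernel_halfwidth
  n <- m$genome$n_bins
  c_bin <- as.integer(floor(center / res)) + 1L
  if (c_bin - hw < 1L || c_bin + hw > n) return(NA_real_)
  band <- oe_band(m, expected, 2L * hw)
  sc <- chin_score_scan(band, n, hw, ignore, cfg$stem_width, cfg$log_eps)
  sc$score[match(c_bin, sc$centers)]
}

# Ridge profile r(d): mean obs/exp over the stem cross-section at
# separation d for a hairpin whose apex sits in bin c_bin. Stem pixels at
# separation d lie near row i = c_bin - d/2.
ridge_profile <- function(band, c_bin, stem_width, max_sep, n) {
  r <- rep(NA_real_, max_sep + 1L)
  for (d in 0:max_sep) {
    ilo <- as.integer(floor(c_bin - d / 2 - stem_width / 2))
    ihi <- as.integer(ceiling(c_bin - d / 2 + stem_width / 2))
    ilo <- max(1L, ilo); ihi <- min(n - d, ihi)
    if (ilo > ihi) next
    v <- band[ilo:ihi, d + 1L]
    if (all(is.na(v))) next
    r[d + 1L] <- mean(v, na.rm = TRUE)
  }
  r
}

# Stem extent by step-fitting the ridge profile: the true profile is
# ~enrichment up to the stem end and ~1 beyond, so the extent is the
# separation maximizing the cumulative excess of the smoothed profile over
# the midpoint between baseline (1) and peak. Robust to local noise dips,
# unlike a first-crossing rule.
estimate_extent <- function(band, c_bin, cfg, ignore, res, n) {
  max_sep <- min(as.integer(cfg$max_extent / res), ncol(band) - 1L)
  r <- ridge_profile(band, c_bin, max(1, cfg$stem_width) + 1, max_sep, n)
  rs <- as.numeric(stats::filter(r, rep(1 / 3, 3), sides = 2))
  rs[is.na(rs)] <- r[is.na(rs)]
  d0 <- max(ignore, 1L)
  dd <- d0:max_sep
  vals <- rs[dd + 1L]
  if (all(is.na(vals))) return(NA_real_)
  peak <- max(vals, na.rm = TRUE)
  if (peak <= 1) return(NA_real_)
  thresh <- 1 + cfg$ridge_frac * (peak - 1)
  excess <- vals - thresh
  excess[is.na(excess)] <- 0
  d_max <- dd[which.max(cumsum(excess))]
  d_max * res
}

#' Detect chromosomal hairpins (CHINs)
#'
#' Scans every bin center with the hairpin kernel, keeps scores at or above
#' `score_threshold`, applies non-maximum suppression within `merge_gap`,
#' and estimates each call's stem extent by following the anti-diagonal
#' ridge outward until the smoothed obs/exp falls below
#' `1 + ridge_frac * (peak - 1)`. Calls with extent below `min_extent` are
#' dropped. Output is deterministic for fixed inputs.
#'
#' @param m A balanced `contact_matrix`.
#' @param expected An [expected_by_distance()] profile.
#' @param cfg A [detect_config()].
#' @return data.frame of class `hairpin_calls`: `center` (bp, apex),
#'   `extent` (bp, stem genomic span), `score`, `start`, `end` (footprint
#'   `center +/- extent/2`). Zero rows when nothing is found.
#' @export
detect_chins <- function(m, expected, cfg = detect_config()) {
  if (!is_balanced(m)) stop("matrix is not balanced; run ice_balance() first")
  res <- m$genome$resolution
  n <- m$genome$n_bins
  ignore <- attr(expected, "ignore_diags")
  hw <- cfg$kernel_halfwidth
  max_sep <- max(2L * hw, as.integer(cfg$max_extent / res))
  band <- oe_band(m, expected, max_sep)
  sc <- chin_score_scan(band, n, hw, ignore, cfg$stem_width, cfg$log_eps)
  centers <- sc$centers
  scores <- sc$score
  cand <- which(!is.na(scores) & scores >= cfg$score_threshold)
  empty <- data.frame(center = numeric(0), extent = numeric(0),
                      score = numeric(0), start = numeric(0), end = numeric(0))
  class(empty) <- c("hairpin_calls", class(empty))
  if (!length(cand)) return(empty)
  ord <- cand[order(scores[cand], decreasing = TRUE)]
  kept <- integer(0)
  gap_bins <- cfg$merge_gap / res
  for (k in ord) {
    if (!length(kept) || all(abs(centers[k] - centers[kept]) > gap_bins)) {
      kept <- c(kept, k)
    }
  }
  rows <- lapply(kept, function(k) {
    ext <- estimate_extent(band, centers[k], cfg, ignore, res, n)
    data.frame(center = (centers[k] - 0.5) * res, extent = ext,
               score = scores[k])
  })
  calls <- do.call(rbind, rows)
  calls <- calls[!is.na(calls$extent) & calls$extent >= cfg$min_extent, , drop = FALSE]
  if (!nrow(calls)) return(empty)
  calls <- calls[order(calls$center), , drop = FALSE]
  calls$start <- pmax(0, calls$center - calls$extent / 2)
  calls$end <- pmin(m$genome$length, calls$center + calls$extent / 2)
  rownames(calls) <- NULL
  class(calls) <- c("hairpin_calls", class(calls))
  calls
}

#' Cluster hairpin calls into hairpin domains (CHIDs)
#'
#' Maximal chains of calls whose footprints lie within `chid_max_gap` of
#' each other and that contain at least `chid_min_members` calls are merged
#' into one interval spanning them.
#'
#' @param calls A `hairpin_calls` table (any order; sorted internally).
#' @param cfg A [detect_config()].
#' @return A `genomic_intervals` table of CHID spans with an `n_members`
#'   column.
#' @export
cluster_chids <- function(calls, cfg = detect_config()) {
  if (!nrow(calls)) {
    return(genomic_intervals(numeric(0), numeric(0)))
  }
  calls <- calls[order(calls$start), , drop = FALSE]
  grp <- integer(nrow(calls)); grp[1] <- 1L
  cur_end <- calls$end[1]
  for (k in seq_len(nrow(calls))[-1]) {
    if (calls$start[k] - cur_end <= cfg$chid_max_gap) {
      grp[k] <- grp[k - 1L]
      cur_end <- max(cur_end, calls$end[k])
    } else {
      grp[k] <- grp[k - 1L] + 1L
      cur_end <- calls$end[k]
    }
  }
  keep <- as.integer(names(which(table(grp) >= cfg$chid_min_members)))
  if (!length(keep)) return(genomic_intervals(numeric(0), numeric(0)))
  s <- vapply(keep, function(g) min(calls$start[grp == g]), numeric(1))
  e <- vapply(keep, function(g) max(calls$end[grp == g]), numeric(1))
  out <- genomic_intervals(s, e, id = sprintf("chid_%d", seq_along(keep)))
  out$n_members <- as.integer(table(grp)[as.character(keep)])
  out
}

# Region obs/exp summaries over cells with |i - j| >= ignore and both bins
# unmasked. "pooled" is sum(balanced)/sum(expected) (a depth-robust mean);
# "median" is the median per-cell obs/exp, robust to localized structures
# (e.g. a hairpin ridge crossing the region). NA when no cell qualifies.
region_oe_stat <- function(m, expected, rows, cols, ignore,
                           stat = c("pooled", "median")) {
  stat <- match.arg(stat)
  blk <- balanced_block(m, rows, cols)
  dmat <- abs(outer(rows, cols, "-"))
  ev <- expected$expected[dmat + 1L]
  dim(ev) <- dim(dmat)
  ok <- !is.na(blk) & !is.na(ev) & dmat >= ignore
  if (!any(ok)) return(NA_real_)
  if (stat == "pooled") sum(blk[ok]) / sum(ev[ok])
  else stats::median(blk[ok] / ev[ok])
}

region_oe_mean <- function(m, expected, rows, cols, ignore) {
  region_oe_stat(m, expected, rows, cols, ignore, "pooled")
}

#' OPCID (square-domain) score of an operon
#'
#' Log median pixel obs/exp inside the operon's on-diagonal square minus
#' the mean log median obs/exp of two same-sized flanking squares.
#' Positive values are domain-like; a flat map scores 0 and a square
#' planted at enrichment `e` scores about `log(e)` at high depth. The
#' median makes the score specific to square domains: a hairpin ridge
#' crossing the region only shifts a minority of pixels and leaves the
#' score near 0.
#'
#' @param m A balanced `contact_matrix`.
#' @param expected An [expected_by_distance()] profile.
#' @param operon One-row interval (`start`, `end` in bp).
#' @return Score (natural log scale), or `NA` when the operon spans fewer
#'   than 4 bins or the regions are fully masked.
#' @export
opcid_score <- function(m, expected, operon) {
  res <- m$genome$resolution
  n <- m$genome$n_bins
  ignore <- attr(expected, "ignore_diags")
  a <- floor(operon$start[1] / res) + 1L
  b <- floor((operon$end[1] - 1) / res) + 1L
  nb <- b - a + 1L
  if (nb < 4L) return(NA_real_)
  inside <- region_oe_stat(m, expected, a:b, a:b, ignore, "median")
  flanks <- c()
  if (a - nb >= 1L) flanks <- c(flanks, region_oe_stat(m, expected, (a - nb):(a - 1L), (a - nb):(a - 1L), ignore, "median"))
  if (b + nb <= n) flanks <- c(flanks, region_oe_stat(m, expected, (b + 1L):(b + nb), (b + 1L):(b + nb), ignore, "median"))
  flanks <- flanks[!is.na(flanks) & flanks > 0]
  if (is.na(inside) || inside <= 0 || !length(flanks)) return(NA_real_)
  log(inside) - mean(log(flanks))
}

#' Inter-hairpin contact score
#'
#' Pooled obs/exp in the off-diagonal rectangle where the stems of two
#' disjoint hairpin calls intersect. A value near 1 means no interaction;
#' planted hairpin-hairpin loops score near their enrichment. Symmetric in
#' its two calls.
#'
#' @param m A balanced `contact_matrix`.
#' @param expected An [expected_by_distance()] profile.
#' @param call_i,call_j One-row slices of a `hairpin_calls` table (must not
#'   overlap).
#' @return Pooled obs/exp, or `NA` when the rectangle is fully masked.
#' @export
chin_contact_score <- function(m, expected, call_i, call_j) {
  if (max(call_i$start[1], call_j$start[1]) < min(call_i$end[1], call_j$end[1])) {
    stop("hairpin calls overlap")
  }
  res <- m$genome$resolution
  n <- m$genome$n_bins
  ignore <- attr(expected, "ignore_diags")
  rows <- (floor(call_i$start[1] / res) + 1L):(floor((call_i$end[1] - 1) / res) + 1L)
  cols <- (floor(call_j$start[1] / res) + 1L):(floor((call_j$end[1] - 1) / res) + 1L)
  rows <- rows[rows >= 1 & rows <= n]; cols <- cols[cols >= 1 & cols <= n]
  region_oe_mean(m, expected, rows, cols, ignore)
}

#' Write hairpin calls as BED and TSV
#' @param calls A `hairpin_calls` table.
#' @param bed_path,tsv_path Output paths (either may be NULL).
#' @param chrom Chromosome name for BED.
#' @export
write_chin_calls <- function(calls, bed_path = NULL, tsv_path = NULL,
                             chrom = "chr") {
  if (!is.null(bed_path)) {
    iv <- genomic_intervals(calls$start, calls$end,
                            id = sprintf("chin_%d", seq_len(nrow(calls))))
    write_bed(iv, bed_path, chrom = chrom)
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(data.table::as.data.table(calls), tsv_path, sep = "\t")
  }
  invisible(calls)
}
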