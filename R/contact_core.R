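# Contact-matrix data model and core matrix statistics.
#
# Storage is sparse upper-triangular (bin_i <= bin_j, 1-indexed) on a single
# chromosome; the symmetric view is materialized lazily for marginal sums.
# Balancing follows ICE (iterative correction): multiplicative per-bin
# weights equalizing the marginals of the balanced matrix, with sparse bins
# masked by the MAD-max filter before iteration.

#' Construct a contact matrix from COO triples
#'
#' @param genome A [genome_spec()].
#' @param i,j 1-based bin indices (any order; stored with i <= j).
#' @param x Non-negative counts.
#' @param weights Optional per-bin balancing weights (NA = masked bin).
#' @return An object of class `contact_matrix` with fields `genome`,
#'   `counts` (a `dgCMatrix`, upper triangle only), `weights` (or NULL when
#'   unbalanced) and `balancing` (convergence metadata).
#' @export
contact_matrix <- function(genome, i, j, x, weights = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  n <- genome$n_bins
  i <- as.integer(i); j <- as.integer(j); x <- as.numeric(x)
  if (length(i) != length(j) || length(i) != length(x)) stop("i, j, x lengths differ")
  if (length(i) && (min(i, j) < 1L || max(i, j) > n)) stop("bin index out of range")
  if (length(x) && any(x < 0)) stop("negative count")
  ii <- pmin(i, j); jj <- pmax(i, j)
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = c(n, n))
  structure(
    list(genome = genome, counts = counts, weights = weights,
         balancing = NULL, cache = new.env(parent = emptyenv())),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d bins @ %d bp, %.0f contacts, %s\n",
    x$genome$n_bins, as.integer(x$genome$resolution), sum(x$counts),
    if (is.null(x$weights)) "unbalanced" else
      sprintf("balanced (%d masked bins)", sum(is.na(x$weights)))
  ))
  invisible(x)
}

is_balanced <- function(m) inherits(m, "contact_matrix") && !is.null(m$weights)

#' Total raw contact count
#' @param m A `contact_matrix`.
#' @export
total_contacts <- function(m) sum(m$counts)

# Full symmetric raw matrix (diagonal counted once).
symmetric_counts <- function(m) {
  u <- m$counts
  u + Matrix::t(u) - Matrix::Diagonal(x = Matrix::diag(u))
}

# Symmetric balanced matrix; masked rows/cols become all-zero (their values
# are undefined and must be guarded by the mask where it matters). Cached
# per matrix object since many statistics query small blocks repeatedly.
symmetric_balanced <- function(m) {
  if (!is_balanced(m)) stop("matrix is not balanced; run ice_balance() first")
  if (!is.null(m$cache$sb)) return(m$cache$sb)
  w <- ifelse(is.na(m$weights), 0, m$weights)
  d <- Matrix::Diagonal(x = w)
  sb <- d %*% symmetric_counts(m) %*% d
  if (!is.null(m$cache)) m$cache$sb <- sb
  sb
}

#' Load contacts from a 4DN pairs file or a COO triple TSV
#'
#' Two plain-text layouts are accepted and auto-detected:
#' * 4DN `.pairs`: whitespace/tab columns
#'   `readID chr1 pos1 chr2 pos2 strand1 strand2`, `#`-prefixed headers
#'   allowed; positions are 0-based bp and are binned by
#'   `floor(pos/resolution)`.
#' * COO TSV: three columns `bin1 bin2 count` (0-based bins), with or
#'   without a header line.
#'
#' @param path File path.
#' @param genome A [genome_spec()] fixing length and resolution.
#' @return An unbalanced `contact_matrix`; its raw total equals the number
#'   of input pairs (or the COO count total).
#' @export
load_contacts <- function(path, genome) {
  stopifnot(inherits(genome, "genome_spec"))
  lines1 <- readLines(path, n = 50L)
  body1 <- lines1[!startsWith(lines1, "#")]
  if (!length(body1)) stop("no data lines in ", path)
  nfield <- length(strsplit(body1[[1]], "[ \t]+")[[1]])
  if (nfield >= 7) load_pairs(path, genome) else load_coo(path, genome)
}

load_pairs <- function(path, genome) {
  dt <- data.table::fread(path, header = FALSE, skip = "\t", sep = "\t")
  if (ncol(dt) < 5) dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 5) stop("pairs file needs >= 5 columns")
  pos1 <- as.numeric(dt[[3]]); pos2 <- as.numeric(dt[[5]])
  bad <- which(!(pos1 >= 0 & pos1 < genome$length & pos2 >= 0 & pos2 < genome$length))
  if (length(bad)) {
    stop(sprintf("out-of-range coordinate at data line %d of %s", bad[1], path))
  }
  chr <- unique(c(as.character(dt[[2]]), as.character(dt[[4]])))
  if (length(chr) > 1) stop("trans-chromosomal pairs are not supported")
  b1 <- floor(pos1 / genome$resolution) + 1
  b2 <- floor(pos2 / genome$resolution) + 1
  contact_matrix(genome, b1, b2, rep(1, length(b1)))
}

load_coo <- function(path, genome) {
  head_lines <- readLines(path, n = 1000L)
  n_comment <- match(FALSE, startsWith(head_lines, "#"), nomatch = 1L) - 1L
  dt <- data.table::fread(path, header = FALSE, skip = n_comment)
  if (is.character(dt[[1]]) && nrow(dt)) dt <- dt[-1, ]  # header line
  if (ncol(dt) < 3) stop("COO file needs 3 columns: bin1 bin2 count")
  b1 <- as.numeric(dt[[1]]); b2 <- as.numeric(dt[[2]]); x <- as.numeric(dt[[3]])
  bad <- which(!(b1 >= 0 & b1 < genome$n_bins & b2 >= 0 & b2 < genome$n_bins))
  if (length(bad)) stop(sprintf("out-of-range bin at data line %d of %s", bad[1], path))
  neg <- which(x < 0)
  if (length(neg)) stop(sprintf("negative count at data line %d of %s", neg[1], path))
  contact_matrix(genome, b1 + 1, b2 + 1, x)
}

#' Write a contact matrix as COO TSV plus a JSON sidecar
#'
#' The TSV holds 0-based `bin1 bin2 count` (upper triangle). The sidecar
#' (`<path>.json`) records the genome, resolution, balancing weights and
#' mask so a balanced matrix round-trips.
#'
#' @param m A `contact_matrix`.
#' @param path Output TSV path.
#' @export
write_contacts <- function(m, path) {
  tr <- as_triplets(m)
  dt <- data.table::data.table(bin1 = tr$i - 1L, bin2 = tr$j - 1L, count = tr$x)
  data.table::fwrite(dt, path, sep = "\t", col.names = TRUE, quote = FALSE)
  side <- list(
    genome = list(name = m$genome$name, length = m$genome$length,
                  resolution = m$genome$resolution, circular = m$genome$circular),
    weights = if (is.null(m$weights)) NULL else as.numeric(m$weights)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @param path TSV path written by [write_contacts()].
#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- genome_spec(side$genome$name, side$genome$length, side$genome$resolution,
                   isTRUE(side$genome$circular))
  m <- load_coo(path, g)
  if (!is.null(side$weights)) m$weights <- as.numeric(side$weights)
  m
}

as_triplets <- function(m) {
  t <- methods::as(m$counts, "TsparseMatrix")
  list(i = t@i + 1L, j = t@j + 1L, x = t@x)
}

# ---- ICE balancing ----------------------------------------------------------

#' ICE balancing (iterative correction)
#'
#' Bins with zero marginal, and bins whose log marginal falls more than
#' `mad_max` median absolute deviations below the median log marginal
#' (under-covered bins: repeats, deleted regions), are masked. The
#' low-side-only filter matches standard balancing practice; masking
#' high-marginal bins as well is available via `mad_side = "both"` but
#' would preferentially remove genuinely enriched structure on
#' narrow-dispersion maps. Remaining weights are iterated until the
#' coefficient of variation of the balanced marginals falls below `tol`,
#' then rescaled so the unmasked balanced marginals have mean 1.
#'
#' @param m An (unbalanced) `contact_matrix`.
#' @param max_iter Iteration cap (default 400).
#' @param tol Convergence tolerance on CV of marginals (default 1e-5).
#' @param mad_max MAD-max mask threshold (default 5).
#' @param mad_side `"low"` (default) or `"both"`.
#' @return The matrix with `weights` set (NA on masked bins) and a
#'   `balancing` list (`iterations`, `cv`, `converged`, `n_masked`).
#' @export
ice_balance <- function(m, max_iter = 400L, tol = 1e-5, mad_max = 5,
                        mad_side = c("low", "both")) {
  stopifnot(inherits(m, "contact_matrix"))
  mad_side <- match.arg(mad_side)
  if (total_contacts(m) <= 0) stop("matrix too sparse to balance")
  s <- symmetric_counts(m)
  marg <- Matrix::rowSums(s)
  mask <- marg <= 0
  nz <- marg[!mask]
  if (length(nz) && mad_max > 0) {
    lm <- log(nz)
    dev <- lm - stats::median(lm)
    if (mad_side == "both") dev <- abs(dev) else dev <- -dev
    cut <- mad_max * stats::median(abs(lm - stats::median(lm)))
    if (cut > 0) {
      bad <- rep(FALSE, length(marg))
      bad[!mask][dev > cut] <- TRUE
      mask <- mask | bad
    }
  }
  if (all(mask)) stop("matrix too sparse to balance")
  w <- ifelse(mask, 0, 1)
  cv <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    bm <- w * as.numeric(s %*% w)  # balanced marginals
    mu <- mean(bm[!mask])
    cv <- stats::sd(bm[!mask]) / mu
    if (is.finite(cv) && cv < tol) break
    adj <- bm / mu
    adj[mask | adj == 0] <- 1
    w <- w / adj
  }
  bm <- w * as.numeric(s %*% w)
  mu <- mean(bm[!mask])
  w <- w / sqrt(mu)
  m$weights <- ifelse(mask, NA_real_, w)
  m$cache <- new.env(parent = emptyenv())  # invalidate cached products
  m$balancing <- list(iterations = it, cv = cv,
                      converged = is.finite(cv) && cv < tol,
                      n_masked = sum(mask), tol = tol, mad_max = mad_max)
  m
}

#' Query balanced values for a rectangular block (dense, NA on masked bins)
#' @noRd
balanced_block <- function(m, rows, cols) {
  if (!is_balanced(m)) stop("matrix is not balanced; run ice_balance() first")
  sb <- symmetric_balanced(m)
  blk <- as.matrix(sb[rows, cols, drop = FALSE])
  wr <- m$weights[rows]; wc <- m$weights[cols]
  blk[is.na(wr), ] <- NA_real_
  blk[, is.na(wc)] <- NA_real_
  blk
}

# ---- expected model ---------------------------------------------------------

#' Distance-decay expected profile
#'
#' Per-diagonal mean of balanced values over pairs with both bins unmasked,
#' plus a smoothed variant aggregated over geometrically spaced distance
#' bins (ratio `geo_ratio`). Inside a geometric bin the smoothed value is
#' the pooled mean `sum(diagonal sums)/sum(valid pairs)`, which preserves
#' total balanced mass per bin exactly; no interpolation is applied.
#' Diagonals `0 .. ignore_diags-1` are undefined.
#'
#' @param m A balanced `contact_matrix`.
#' @param ignore_diags Number of leading diagonals to drop (default 2).
#' @param geo_ratio Geometric bin ratio for smoothing (default 1.05).
#' @return An object of class `expected_profile`: data.frame-backed with
#'   per-diagonal `dist_bins`, `expected`, `expected_smoothed`,
#'   `valid_pairs`, plus attributes `ignore_diags` and `resolution`.
#' @export
expected_by_distance <- function(m, ignore_diags = 2L, geo_ratio = 1.05) {
  if (!is_balanced(m)) stop("matrix is not balanced; run ice_balance() first")
  n <- m$genome$n_bins
  w <- m$weights
  unmasked <- !is.na(w)
  tr <- as_triplets(m)
  keep <- unmasked[tr$i] & unmasked[tr$j]
  d <- tr$j[keep] - tr$i[keep]
  val <- tr$x[keep] * w[tr$i[keep]] * w[tr$j[keep]]
  dsum <- numeric(n)  # index d+1
  if (length(d)) {
    agg <- rowsum(val, d)
    dsum[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  valid <- valid_pairs_per_diag(unmasked)
  e <- ifelse(valid > 0, dsum / valid, NA_real_)
  dvec <- 0:(n - 1L)
  e[dvec < ignore_diags] <- NA_real_
  es <- smooth_expected(dsum, valid, ignore_diags, geo_ratio)
  out <- data.frame(dist_bins = dvec, expected = e, expected_smoothed = es,
                    valid_pairs = valid)
  attr(out, "ignore_diags") <- as.integer(ignore_diags)
  attr(out, "resolution") <- m$genome$resolution
  class(out) <- c("expected_profile", class(out))
  out
}

# Number of (i, i+d) pairs with both bins unmasked, for d = 0..n-1,
# via FFT autocorrelation of the unmasked indicator.
valid_pairs_per_diag <- function(unmasked) {
  n <- length(unmasked)
  u <- as.numeric(unmasked)
  np <- stats::nextn(2L * n, 2)
  fu <- stats::fft(c(u, rep(0, np - n)))
  ac <- Re(stats::fft(fu * Conj(fu), inverse = TRUE)) / np
  round(ac[1:n])
}

smooth_expected <- function(dsum, valid, ignore_diags, geo_ratio) {
  n <- length(dsum)
  es <- rep(NA_real_, n)
  d0 <- max(as.integer(ignore_diags), 0L)
  if (d0 >= n) return(es)
  edges <- d0
  cur <- max(d0, 1)
  while (cur < n) {
    nxt <- max(cur + 1L, as.integer(floor(cur * geo_ratio)))
    edges <- c(edges, min(nxt, n))
    cur <- nxt
  }
  if (edges[length(edges)] < n) edges <- c(edges, n)
  for (k in seq_len(length(edges) - 1L)) {
    idx <- (edges[k]:(edges[k + 1L] - 1L)) + 1L
    vp <- sum(valid[idx])
    if (vp > 0) es[idx] <- sum(dsum[idx]) / vp
  }
  es
}

#' Contact-probability scaling curve P(s)
#'
#' Mean contact frequency per bin pair versus genomic separation, in
#' log-spaced distance bins (each bin pools raw counts over its diagonals
#' and divides by the number of bin pairs at those separations), then
#' normalized so the integral (probability density times bin width in bp)
#' over distances >= `min_dist` equals 1. Intended for log-log plotting:
#' a planted power-law decay with exponent alpha reproduces a log-log
#' slope of -alpha.
#'
#' @param m A `contact_matrix` (raw counts are used).
#' @param min_dist Minimum separation in bp (default 100); shorter-range
#'   contacts are excluded.
#' @param bins_per_decade Log-spaced bins per decade of distance (default 25).
#' @return data.frame with `dist_bp` (geometric bin midpoint), `prob`
#'   (normalized density per bp) and `n_contacts`.
#' @export
scaling_curve <- function(m, min_dist = 100, bins_per_decade = 25) {
  stopifnot(inherits(m, "contact_matrix"))
  res <- m$genome$resolution
  n <- m$genome$n_bins
  tr <- as_triplets(m)
  d_bp <- (tr$j - tr$i) * res
  keep <- d_bp >= min_dist
  if (!any(keep) || sum(tr$x[keep]) == 0) stop("no contacts beyond min_dist")
  d_bp <- d_bp[keep]; x <- tr$x[keep]
  lo <- log10(max(min_dist, res)); hi <- log10(max(d_bp) + res)
  edges <- 10^seq(lo, hi, length.out = max(2L, ceiling((hi - lo) * bins_per_decade) + 1L))
  bin <- findInterval(d_bp, edges, rightmost.closed = TRUE)
  csum <- tapply(x, bin, sum)
  idx <- as.integer(names(csum))
  # bin pairs available per log-distance bin
  all_d <- (ceiling(min_dist / res):(n - 1L)) * res
  all_bin <- findInterval(all_d, edges, rightmost.closed = TRUE)
  pairs_per_bin <- tapply(n - all_d / res, all_bin, sum)
  npairs <- as.numeric(pairs_per_bin[match(idx, as.integer(names(pairs_per_bin)))])
  width <- edges[idx + 1L] - edges[idx]
  mid <- sqrt(edges[idx] * edges[idx + 1L])
  freq <- as.numeric(csum) / npairs            # mean contacts per bin pair
  prob <- freq / sum(freq * width)             # integral over s >= min_dist is 1
  data.frame(dist_bp = mid, prob = prob, n_contacts = as.numeric(csum))
}

# ---- stratum-adjusted correlation (SCC) -------------------------------------

#' Configuration for the stratum-adjusted correlation coefficient
#'
#' @param h Mean-filter smoothing half-width in bins (default 30, matching
#'   common practice at 100 bp resolution).
#' @param max_dist Maximum separation in bp entering the strata (default
#'   5,000). The default covers the scale at which this system's
#'   distance-detrended structure lives (hairpin stems and operon domains
#'   are a few kb); strata far beyond the structure scale contribute only
#'   Poisson noise to the correlation.
#' @return A list of class `scc_config`.
#' @export
scc_config <- function(h = 30L, max_dist = 5000) {
  stopifnot(h >= 0, max_dist > 0)
  structure(list(h = as.integer(h), max_dist = max_dist), class = "scc_config")
}

#' Stratum-adjusted correlation coefficient between two contact maps
#'
#' Raw counts of both maps are smoothed with a 2D mean filter of half-width
#' `h` (truncated at matrix borders); per-diagonal Pearson correlations are
#' then combined with weights `N_d * sqrt(var(rank(x)/N) * var(rank(y)/N))`
#' (the variance-stabilized rank transform weighting of the published SCC).
#'
#' @param m1,m2 `contact_matrix` objects on the same genome and resolution.
#' @param cfg An [scc_config()].
#' @return SCC in `[-1, 1]`; `scc(M, M)` is exactly 1.
#' @export
scc <- function(m1, m2, cfg = scc_config()) {
  stopifnot(inherits(m1, "contact_matrix"), inherits(m2, "contact_matrix"))
  if (m1$genome$resolution != m2$genome$resolution ||
      m1$genome$n_bins != m2$genome$n_bins) {
    stop("resolution mismatch between contact matrices")
  }
  n <- m1$genome$n_bins
  if (n > 20000) stop("scc: matrix too large for dense smoothing")
  a <- box_smooth(as.matrix(symmetric_counts(m1)), cfg$h)
  b <- box_smooth(as.matrix(symmetric_counts(m2)), cfg$h)
  dmax <- min(n - 1L, as.integer(floor(cfg$max_dist / m1$genome$resolution)))
  num <- 0; den <- 0
  for (d in 1:dmax) {
    idx <- seq_len(n - d)
    x <- a[cbind(idx, idx + d)]
    y <- b[cbind(idx, idx + d)]
    if (length(x) < 2) next
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx == 0 || sy == 0) next
    rho <- stats::cor(x, y)
    nd <- length(x)
    # ranks on values rounded to 9 significant digits: tie structure (and
    # hence the variance-stabilized weights) must not depend on float
    # noise of the smoothing implementation
    r2 <- sqrt(stats::var(rank(signif(x, 9)) / nd) *
               stats::var(rank(signif(y, 9)) / nd))
    wgt <- nd * r2
    num <- num + wgt * rho
    den <- den + wgt
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Separable truncated-window mean filter via cumulative sums.
box_smooth <- function(mat, h) {
  if (h <= 0) return(mat)
  smooth1 <- function(m) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  t(smooth1(t(smooth1(mat))))
}
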