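# Synthetic nucleoid generator.
#
# A "truth" is a full parameterization of a synthetic bacterial nucleoid:
# a power-law distance decay with multiplicative feature enrichments
# (hairpins = anti-diagonal ridges, operon domains = on-diagonal squares
# with a promoter-terminator corner dot whose strength grows with planted
# activity, hairpin-hairpin loops = off-diagonal dots), plus planted
# operon activities, HTG islands hosting all hairpins, and seeds for every
# sampling stream. Contact maps are Poisson samples of the resulting
# intensity, so analytic expectations are available for every test.
#
# The default world is a 500 kb chromosome at 100 bp resolution
# (5,000 bins) with 2e6 contacts: large enough to host dozens of features,
# small enough for seconds-scale tests. A full-length 4,641,652 bp mode is
# available by overriding `genome_length`.

#' Simulation configuration
#'
#' Defaults state the simulated world: they are chosen once to emulate the
#' reference system (hairpin extents lognormal around a 2 kb median within
#' 0.5-6 kb, Red-C displacement with 90% of its mass within 10 kb,
#' bimodal H-NS-like stem signal) and are not tuned per test.
#'
#' @param genome_length Chromosome length in bp (default 500,000).
#' @param resolution Bin size in bp (default 100).
#' @param alpha Power-law distance-decay exponent (default 1.1).
#' @param base_depth Total expected contact pairs (default 2e6).
#' @param n_operons Number of operons (default 60).
#' @param operon_length_meanlog,operon_length_sdlog Lognormal operon
#'   lengths (default median 2 kb, sdlog 0.35; clipped to 600-8,000 bp).
#' @param frac_zero_activity Fraction of transcriptionally silent operons
#'   (default 0.3).
#' @param redc_depth Expected total Red-C contacts (default 1e5); nonzero
#'   activity rates are lognormal and rescaled to this total.
#' @param n_htg_islands Number of AT-rich horizontally-transferred-gene
#'   islands (default 6); all hairpins are placed inside islands.
#' @param htg_island_length Island length in bp (default 25,000).
#' @param n_chins Number of isolated hairpins (default 10).
#' @param chin_extent_meanlog,chin_extent_sdlog Lognormal stem extents
#'   (default median 2 kb, sdlog 0.5; clipped to 500-6,000 bp).
#' @param chin_enrichment Stem obs/exp enrichment (default 3).
#' @param chin_stem_width Stem cross-section width in bins (default 2).
#' @param stem_min_sep Smallest stem separation in bp (default
#'   2 * resolution, matching the ignored diagonals).
#' @param n_chids Number of hairpin domains (default 2).
#' @param chid_members Alternative hairpins per domain (default 4).
#' @param n_chin_pairs Number of hairpin-hairpin loops (default 2).
#' @param chin_pair_enrichment Loop dot enrichment (default 3).
#' @param n_opcids Number of operon domains, assigned to the most active
#'   operons (default 15).
#' @param opcid_enrichment Square-domain enrichment (default 2).
#' @param corner_gain Corner-dot strength gain: strength =
#'   1 + corner_gain * activity_density / median(active densities)
#'   (default 2), a fixed monotone map from planted activity.
#' @param corner_sd Corner-dot Gaussian sd in bp (default 200).
#' @param operons,opcids,chins,chin_pairs Optional explicit feature tables
#'   overriding random placement (see [make_truth()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 500000, resolution = 100,
                       alpha = 1.1, base_depth = 2e6,
                       n_operons = 60L,
                       operon_length_meanlog = log(2000),
                       operon_length_sdlog = 0.35,
                       frac_zero_activity = 0.3,
                       redc_depth = 1e5,
                       n_htg_islands = 6L, htg_island_length = 25000,
                       n_chins = 10L,
                       chin_extent_meanlog = log(2000),
                       chin_extent_sdlog = 0.5,
                       chin_enrichment = 3, chin_stem_width = 2L,
                       stem_min_sep = NULL,
                       n_chids = 2L, chid_members = 4L,
                       n_chin_pairs = 2L, chin_pair_enrichment = 3,
                       n_opcids = 15L, opcid_enrichment = 2,
                       corner_gain = 2, corner_sd = 200,
                       operons = NULL, opcids = NULL, chins = NULL,
                       chin_pairs = NULL) {
  if (is.null(stem_min_sep)) stem_min_sep <- 2 * resolution
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Assemble and validate a simulation truth
#'
#' Normally called through [make_truth()]; exposed so tests can plant
#' features at exact coordinates.
#'
#' @param genome A `genome_spec`.
#' @param alpha,base_depth Decay exponent and expected total contacts.
#' @param operons An `operon_table` with an `activity` column (expected
#'   Red-C contacts per bp per operon).
#' @param opcids data.frame: `start`, `end`, `tss`, `tes`,
#'   `domain_enrichment`, `corner_strength`, `corner_sd` (bp).
#' @param chins data.frame: `center`, `extent` (bp), `enrichment`,
#'   `stem_width` (bins), `chid` (0 = isolated, else domain id).
#' @param chin_pairs data.frame: `i`, `j` (row indices into `chins`),
#'   `enrichment`, `sd` (bp).
#' @param htg_islands A `genomic_intervals` table.
#' @param stem_min_sep Smallest stem separation in bp.
#' @param seed Base seed; per-stream seeds are derived from it.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(genome, alpha, base_depth, operons, opcids, chins,
                      chin_pairs, htg_islands, stem_min_sep, seed) {
  stopifnot(inherits(genome, "genome_spec"))
  if (nrow(chins)) {
    stopifnot(all(chins$center - chins$extent / 2 >= 0),
              all(chins$center + chins$extent / 2 <= genome$length),
              all(chins$enrichment >= 1))
    if (nrow(htg_islands)) {
      inside <- vapply(seq_len(nrow(chins)), function(k) {
        any(chins$center[k] - chins$extent[k] / 2 >= htg_islands$start &
            chins$center[k] + chins$extent[k] / 2 <= htg_islands$end)
      }, logical(1))
      if (!all(inside)) stop("every hairpin must lie inside an HTG island")
    }
  }
  if (nrow(opcids)) stopifnot(all(opcids$domain_enrichment >= 1),
                              all(opcids$corner_strength >= 1),
                              all(opcids$end <= genome$length))
  structure(
    list(genome = genome, alpha = alpha, base_depth = base_depth,
         operons = operons, opcids = opcids, chins = chins,
         chin_pairs = chin_pairs, htg_islands = htg_islands,
         stem_min_sep = stem_min_sep,
         seeds = list(contacts = derive_seed(seed, 1L),
                      redc = derive_seed(seed, 2L),
                      chip = derive_seed(seed, 3L)),
         base_seed = as.integer(seed)),
    class = "sim_truth"
  )
}

# Greedy non-overlapping placement of n intervals of given lengths within
# [lo, hi); returns starts or errors after bounded retries.
place_nonoverlapping <- function(n, lengths, lo, hi, gap = 0, occupied = NULL,
                                 max_try = 2000L) {
  starts <- numeric(0); ends <- numeric(0)
  if (!is.null(occupied) && nrow(occupied)) {
    starts <- occupied$start; ends <- occupied$end
  }
  out <- numeric(n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      s <- floor(stats::runif(1, lo, hi - lengths[k]))
      e <- s + lengths[k]
      if (!length(starts) || all(e + gap <= starts | s - gap >= ends)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible packing of simulated features")
    out[k] <- s
    starts <- c(starts, s); ends <- c(ends, s + lengths[k])
  }
  out
}

#' Generate a random simulation truth
#'
#' Deterministic for a fixed seed: HTG islands are placed first, hairpins
#' (isolated and domain members) inside them, operons outside, activities
#' drawn and rescaled to `redc_depth`, operon domains assigned to the most
#' active operons with corner-dot strength a fixed monotone function of
#' activity, and hairpin-hairpin loops between isolated hairpins.
#'
#' @param config A [sim_config()].
#' @param seed Integer base seed.
#' @return A `sim_truth`.
#' @export
make_truth <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  g <- genome_spec("sim", config$genome_length, config$resolution,
                   circular = TRUE)
  with_seed(derive_seed(seed, 0L), {
    truth_body(config, g, seed)
  })
}

truth_body <- function(config, g, seed) {
  L <- g$length
  margin <- min(0.02 * L, 10000)
  # --- HTG islands and hairpins ---
  if (is.null(config$chins)) {
    n_isl <- config$n_htg_islands
    isl_len <- rep(config$htg_island_length, n_isl)
    isl_start <- place_nonoverlapping(n_isl, isl_len, margin, L - margin,
                                      gap = config$htg_island_length / 2)
    islands <- genomic_intervals(isl_start, isl_start + isl_len,
                                 id = sprintf("htg_%d", seq_len(n_isl)),
                                 genome = g)
    chins <- make_chins(config, islands)
  } else {
    chins <- config$chins
    if (is.null(chins$chid)) chins$chid <- rep(0L, nrow(chins))
    if (is.null(chins$stem_width)) {
      chins$stem_width <- rep(config$chin_stem_width, nrow(chins))
    }
    if (is.null(chins$enrichment)) {
      chins$enrichment <- rep(config$chin_enrichment, nrow(chins))
    }
    islands <- genomic_intervals(chins$center - chins$extent / 2,
                                 chins$center + chins$extent / 2,
                                 id = if (nrow(chins))
                                   sprintf("htg_%d", seq_len(nrow(chins)))
                                 else character(0))
  }
  # --- operons ---
  if (is.null(config$operons)) {
    ops <- make_operons(config, g, islands, margin)
  } else {
    o <- config$operons
    ops <- operon_table(o$start, o$end, o$strand, id = o$id, genome = g)
    ops$activity <- o$activity
  }
  # --- OPCIDs on the most active operons ---
  if (is.null(config$opcids)) {
    opcids <- make_opcids(config, ops)
  } else {
    opcids <- config$opcids
  }
  # --- hairpin-hairpin loops ---
  if (is.null(config$chin_pairs)) {
    iso <- which(chins$chid == 0L)
    np <- min(config$n_chin_pairs, floor(length(iso) / 2))
    chin_pairs <- if (np > 0) {
      data.frame(i = iso[seq_len(np) * 2 - 1], j = iso[seq_len(np) * 2],
                 enrichment = rep(config$chin_pair_enrichment, np),
                 sd = rep(3 * g$resolution, np))
    } else {
      data.frame(i = integer(0), j = integer(0), enrichment = numeric(0),
                 sd = numeric(0))
    }
  } else {
    chin_pairs <- config$chin_pairs
  }
  sim_truth(g, config$alpha, config$base_depth, ops, opcids, chins,
            chin_pairs, islands, config$stem_min_sep, seed)
}

make_chins <- function(config, islands) {
  n_iso <- config$n_chins
  n_chid <- config$n_chids
  mem <- config$chid_members
  draw_extent <- function(n) {
    pmin(pmax(stats::rlnorm(n, config$chin_extent_meanlog,
                            config$chin_extent_sdlog), 500), 6000)
  }
  rows <- list()
  # domains first: each occupies one island; members are alternative
  # overlapping hairpins with staggered centers
  chid_islands <- seq_len(min(n_chid, nrow(islands)))
  for (d in chid_islands) {
    isl <- islands[d, ]
    ext <- draw_extent(mem)
    spacing <- 1500  # apexes resolvable at 100 bp maps, footprints overlap
    span <- (mem - 1) * spacing + max(ext)
    c0 <- stats::runif(1, isl$start + span / 2, isl$end - span / 2)
    centers <- c0 + (seq_len(mem) - (mem + 1) / 2) * spacing
    for (k in seq_len(mem)) {
      rows[[length(rows) + 1L]] <- data.frame(
        center = centers[k], extent = ext[k],
        enrichment = config$chin_enrichment,
        stem_width = config$chin_stem_width, chid = d)
    }
  }
  # isolated hairpins on the remaining islands (round-robin), non-overlapping
  free <- setdiff(seq_len(nrow(islands)), chid_islands)
  if (length(free) && n_iso > 0) {
    ext <- draw_extent(n_iso)
    per_isl <- split(seq_len(n_iso), rep_len(free, n_iso))
    for (isl_id in names(per_isl)) {
      isl <- islands[as.integer(isl_id), ]
      idx <- per_isl[[isl_id]]
      starts <- place_nonoverlapping(length(idx), ext[idx], isl$start,
                                     isl$end, gap = 500)
      for (q in seq_along(idx)) {
        rows[[length(rows) + 1L]] <- data.frame(
          center = starts[q] + ext[idx[q]] / 2, extent = ext[idx[q]],
          enrichment = config$chin_enrichment,
          stem_width = config$chin_stem_width, chid = 0L)
      }
    }
  }
  do.call(rbind, rows)
}

make_operons <- function(config, g, islands, margin) {
  n <- config$n_operons
  len <- pmin(pmax(stats::rlnorm(n, config$operon_length_meanlog,
                                 config$operon_length_sdlog), 600), 8000)
  starts <- place_nonoverlapping(n, len, margin, g$length - margin,
                                 gap = 200, occupied = islands)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ops <- operon_table(starts, starts + len, strand,
                      id = sprintf("op_%d", seq_len(n)), genome = g)
  zero <- stats::runif(n) < config$frac_zero_activity
  raw <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  raw[zero] <- 0
  tot <- sum(raw * len)
  ops$activity <- if (tot > 0) raw * config$redc_depth / tot else raw
  ops
}

make_opcids <- function(config, ops) {
  dens <- ops$activity  # planted activity is a per-bp rate
  idx <- order(dens, decreasing = TRUE)[seq_len(min(config$n_opcids, sum(dens > 0)))]
  if (!length(idx)) {
    return(data.frame(start = numeric(0), end = numeric(0), tss = numeric(0),
                      tes = numeric(0), domain_enrichment = numeric(0),
                      corner_strength = numeric(0), corner_sd = numeric(0)))
  }
  med <- stats::median(dens[idx])
  data.frame(
    start = ops$start[idx], end = ops$end[idx],
    tss = ops$tss[idx], tes = ops$tes[idx],
    domain_enrichment = rep(config$opcid_enrichment, length(idx)),
    corner_strength = 1 + config$corner_gain * dens[idx] / med,
    corner_sd = rep(config$corner_sd, length(idx))
  )
}

# ---- intensity model --------------------------------------------------------

# Per-feature multiplier spans in diagonal (separation) space, so each
# diagonal only visits the features that can touch it.
feature_spans <- function(truth) {
  res <- truth$genome$resolution
  feats <- list()
  add <- function(f, dmin, dmax) {
    f$dmin <- max(0L, as.integer(dmin)); f$dmax <- as.integer(dmax)
    feats[[length(feats) + 1L]] <<- f
  }
  ch <- truth$chins
  for (k in seq_len(nrow(ch))) {
    add(list(type = "chin", cb = ch$center[k] / res, w = ch$stem_width[k],
             e = ch$enrichment[k]),
        ceiling(truth$stem_min_sep / res), floor(ch$extent[k] / res))
  }
  opc <- truth$opcids
  for (k in seq_len(nrow(opc))) {
    a <- floor(opc$start[k] / res) + 1L
    b <- floor((opc$end[k] - 1) / res) + 1L
    add(list(type = "square", a = a, b = b, e = opc$domain_enrichment[k]),
        0L, b - a)
    if (opc$corner_strength[k] > 1) {
      t1 <- min(opc$tss[k], opc$tes[k]) / res + 0.5
      t2 <- max(opc$tss[k], opc$tes[k]) / res + 0.5
      sd <- max(opc$corner_sd[k] / res, 0.5)
      add(list(type = "dot", ci = t1, cj = t2, s = opc$corner_strength[k],
               sd = sd),
          floor(t2 - t1 - 4 * sd), ceiling(t2 - t1 + 4 * sd))
    }
  }
  cp <- truth$chin_pairs
  for (k in seq_len(nrow(cp))) {
    ci <- truth$chins$center[cp$i[k]] / res + 0.5
    cj <- truth$chins$center[cp$j[k]] / res + 0.5
    if (ci > cj) { tmp <- ci; ci <- cj; cj <- tmp }
    sd <- max(cp$sd[k] / res, 0.5)
    add(list(type = "dot", ci = ci, cj = cj, s = cp$enrichment[k], sd = sd),
        floor(cj - ci - 4 * sd), ceiling(cj - ci + 4 * sd))
  }
  feats
}

# Multiplier vector for diagonal d: entries i = 1..n-d, j = i + d.
diag_multiplier <- function(feats_by_d, feats, d, n) {
  v <- rep(1, n - d)
  for (fi in feats_by_d[[d + 1L]]) {
    f <- feats[[fi]]
    if (f$type == "chin") {
      # stem condition |i + j - 1 - 2*cb| <= w with j = i + d
      lo <- ceiling(f$cb + (1 - d - f$w) / 2)
      hi <- floor(f$cb + (1 - d + f$w) / 2)
      lo <- max(1L, lo); hi <- min(n - d, hi)
      if (lo <= hi) v[lo:hi] <- v[lo:hi] * f$e
    } else if (f$type == "square") {
      lo <- f$a; hi <- f$b - d
      if (lo <= hi && lo <= n - d) {
        hi <- min(hi, n - d)
        v[lo:hi] <- v[lo:hi] * f$e
      }
    } else if (f$type == "dot") {
      lo <- max(1L, floor(f$ci - 4 * f$sd))
      hi <- min(n - d, ceiling(f$ci + 4 * f$sd))
      if (lo <= hi) {
        i <- lo:hi
        gauss <- exp(-((i - f$ci)^2 + (i + d - f$cj)^2) / (2 * f$sd^2))
        v[i] <- v[i] * (1 + (f$s - 1) * gauss)
      }
    }
  }
  v
}

#' Expected contact intensity of a truth
#'
#' The intensity is `lambda(i, j) = C * max(|i - j|, 1)^(-alpha)` times the
#' product of all feature multipliers, with `C` normalized so the upper
#' triangle sums to `base_depth`. Returned as a lazy per-diagonal model;
#' use [lambda_diag()] for one diagonal or [as_dense_lambda()] (small
#' genomes only) for the full symmetric matrix.
#'
#' @param truth A `sim_truth`.
#' @return An object of class `expected_map`.
#' @export
expected_map_from_truth <- function(truth) {
  n <- truth$genome$n_bins
  feats <- feature_spans(truth)
  feats_by_d <- vector("list", n)
  for (fi in seq_along(feats)) {
    f <- feats[[fi]]
    dmin <- max(0L, f$dmin); dmax <- min(n - 1L, f$dmax)
    if (dmin > dmax) next
    for (d in dmin:dmax) feats_by_d[[d + 1L]] <- c(feats_by_d[[d + 1L]], fi)
  }
  total <- 0
  for (d in 0:(n - 1L)) {
    total <- total + max(d, 1)^(-truth$alpha) *
      sum(diag_multiplier(feats_by_d, feats, d, n))
  }
  structure(list(truth = truth, C = truth$base_depth / total, n = n,
                 feats = feats, feats_by_d = feats_by_d),
            class = "expected_map")
}

#' @param em An `expected_map`.
#' @param d Diagonal (separation in bins, 0-based).
#' @return `lambda_diag`: numeric vector of intensities for pairs
#'   `(i, i + d)`, `i = 1..n-d`.
#' @rdname expected_map_from_truth
#' @export
lambda_diag <- function(em, d) {
  em$C * max(d, 1)^(-em$truth$alpha) *
    diag_multiplier(em$feats_by_d, em$feats, d, em$n)
}

#' @rdname expected_map_from_truth
#' @export
as_dense_lambda <- function(em) {
  n <- em$n
  if (n > 3000) stop("dense lambda only supported for small genomes")
  out <- matrix(0, n, n)
  for (d in 0:(n - 1L)) {
    lam <- lambda_diag(em, d)
    i <- seq_len(n - d)
    out[cbind(i, i + d)] <- lam
    out[cbind(i + d, i)] <- lam
  }
  out
}

#' Sample a contact map from a truth
#'
#' Independent Poisson draws of the upper-triangle intensity, seeded by
#' `truth$seeds$contacts` (bit-identical across runs).
#'
#' @param truth A `sim_truth`.
#' @param em Optional precomputed [expected_map_from_truth()].
#' @return An unbalanced `contact_matrix`.
#' @export
sample_contact_map <- function(truth, em = NULL) {
  if (is.null(em)) em <- expected_map_from_truth(truth)
  n <- truth$genome$n_bins
  is <- vector("list", n); js <- vector("list", n); xs <- vector("list", n)
  with_seed(truth$seeds$contacts, {
    for (d in 0:(n - 1L)) {
      lam <- lambda_diag(em, d)
      x <- stats::rpois(length(lam), lam)
      nz <- which(x > 0)
      if (length(nz)) {
        is[[d + 1L]] <- nz; js[[d + 1L]] <- nz + d; xs[[d + 1L]] <- x[nz]
      }
    }
  })
  contact_matrix(truth$genome, unlist(is), unlist(js), unlist(xs))
}

#' Simulate Red-C RNA-DNA contacts from a truth
#'
#' Per-operon contact counts are Poisson with mean `activity * length`;
#' RNA positions are uniform within the operon and DNA positions are the
#' RNA position plus a zero-mean Gaussian displacement whose sd puts 90%
#' of its mass within 10 kb (sd = 10,000 / qnorm(0.95)), clipped to the
#' genome.
#'
#' @param truth A `sim_truth`.
#' @return A `redc_contacts` table.
#' @export
simulate_redc <- function(truth) {
  ops <- truth$operons
  g <- truth$genome
  sd_disp <- 10000 / stats::qnorm(0.95)
  rna <- numeric(0); dna <- numeric(0)
  with_seed(truth$seeds$redc, {
    for (k in seq_len(nrow(ops))) {
      nk <- stats::rpois(1, ops$activity[k] * (ops$end[k] - ops$start[k]))
      if (nk == 0) next
      r <- floor(stats::runif(nk, ops$start[k], ops$end[k]))
      d <- r + stats::rnorm(nk, 0, sd_disp)
      d <- pmin(pmax(floor(d), 0), g$length - 1)
      rna <- c(rna, r); dna <- c(dna, d)
    }
  })
  redc_contacts(rna, dna, 1, genome = g)
}

#' Simulate a ChIP-like signal track from a truth
#'
#' `"hns_like"`: bimodal Gaussian bumps on each hairpin's two stem arms
#' (bump centers at `center +/- extent/4`, sd `extent/8`) over a flat noise
#' floor - peaks on the stems with a drop at the apex. `"rnap_like"`:
#' plateaus over operons scaled by planted activity. Per-bin values are
#' Poisson-sampled (seeded).
#'
#' @param truth A `sim_truth`.
#' @param target `"hns_like"` or `"rnap_like"`.
#' @param bin_size Track bin width in bp (default: matrix resolution).
#' @param noise_floor Background Poisson mean per bin (default 2).
#' @param amplitude Peak mean over the floor (default 30).
#' @return A [signal_track()].
#' @export
simulate_chip_track <- function(truth, target = c("hns_like", "rnap_like"),
                                bin_size = NULL, noise_floor = 2,
                                amplitude = 30) {
  target <- match.arg(target)
  g <- truth$genome
  if (is.null(bin_size)) bin_size <- g$resolution
  n <- as.integer(ceiling(g$length / bin_size))
  pos <- (seq_len(n) - 0.5) * bin_size
  mu <- rep(noise_floor, n)
  if (target == "hns_like") {
    ch <- truth$chins
    for (k in seq_len(nrow(ch))) {
      for (arm in c(-1, 1)) {
        bc <- ch$center[k] + arm * ch$extent[k] / 4
        sd <- max(ch$extent[k] / 8, bin_size)
        mu <- mu + amplitude * exp(-(pos - bc)^2 / (2 * sd^2))
      }
    }
  } else {
    ops <- truth$operons
    act <- ops$activity
    scale <- if (any(act > 0)) stats::median(act[act > 0]) else 1
    for (k in seq_len(nrow(ops))) {
      if (act[k] <= 0) next
      sel <- pos >= ops$start[k] & pos < ops$end[k]
      mu[sel] <- mu[sel] + amplitude * act[k] / scale
    }
  }
  with_seed(derive_seed(truth$seeds$chip, if (target == "hns_like") 0L else 1L), {
    vals <- stats::rpois(n, mu)
  })
  signal_track(vals, bin_size)
}

#' Ground-truth feature tables of a truth (for benchmarking detectors)
#'
#' @param truth A `sim_truth`.
#' @return List of `genomic_intervals`: `chins` (stem footprints, with
#'   `center`/`extent` columns), `chids` (union spans of member hairpins),
#'   `opcids`, `htg_islands`.
#' @export
truth_features <- function(truth) {
  ch <- truth$chins
  chin_iv <- genomic_intervals(ch$center - ch$extent / 2,
                               ch$center + ch$extent / 2,
                               id = sprintf("chin_%d", seq_len(nrow(ch))))
  chin_iv$center <- ch$center; chin_iv$extent <- ch$extent
  chin_iv$chid <- ch$chid
  chids <- NULL
  for (d in setdiff(unique(ch$chid), 0L)) {
    sel <- ch$chid == d
    chids <- rbind(chids, data.frame(
      start = min(ch$center[sel] - ch$extent[sel] / 2),
      end = max(ch$center[sel] + ch$extent[sel] / 2)))
  }
  chids <- if (is.null(chids)) genomic_intervals(numeric(0), numeric(0))
           else genomic_intervals(chids$start, chids$end,
                                  id = sprintf("chid_%d", seq_len(nrow(chids))))
  opcids <- genomic_intervals(truth$opcids$start, truth$opcids$end,
                              id = if (nrow(truth$opcids))
                                sprintf("opcid_%d", seq_len(nrow(truth$opcids)))
                              else character(0))
  list(chins = chin_iv, chids = chids, opcids = opcids,
       htg_islands = truth$htg_islands)
}

#' Serialize / restore a truth as JSON
#' @param truth A `sim_truth`.
#' @param path JSON path.
#' @rdname truth_json
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(genome = list(name = truth$genome$name, length = truth$genome$length,
                       resolution = truth$genome$resolution,
                       circular = truth$genome$circular),
         alpha = truth$alpha, base_depth = truth$base_depth,
         stem_min_sep = truth$stem_min_sep,
         operons = truth$operons, opcids = truth$opcids,
         chins = truth$chins, chin_pairs = truth$chin_pairs,
         htg_islands = as.data.frame(truth$htg_islands),
         seeds = truth$seeds, base_seed = truth$base_seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname truth_json
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- genome_spec(j$genome$name, j$genome$length, j$genome$resolution,
                   isTRUE(j$genome$circular))
  ops <- operon_table(j$operons$start, j$operons$end, j$operons$strand,
                      id = j$operons$id, sigma = j$operons$sigma,
                      redc_signal = j$operons$redc_signal, genome = g)
  ops$activity <- j$operons$activity
  tr <- sim_truth(g, j$alpha, j$base_depth, ops,
                  as.data.frame(j$opcids), as.data.frame(j$chins),
                  as.data.frame(j$chin_pairs),
                  validate_intervals(as.data.frame(j$htg_islands), g),
                  j$stem_min_sep, j$base_seed)
  tr$seeds <- j$seeds
  tr
}
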