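# World with isolated planted hairpins at known coordinates, no other
# features, used across the detection tests.
hairpin_world <- function(seed, centers, extents, enrichment = 3,
                          genome_length = 200000, depth = 8e5) {
  cfg <- sim_config(
    genome_length = genome_length, base_depth = depth,
    operons = data.frame(start = 1000, end = 3000, strand = "+",
                         id = "op_1", activity = 0),
    opcids = data.frame(start = numeric(0), end = numeric(0),
                        tss = numeric(0), tes = numeric(0),
                        domain_enrichment = numeric(0),
                        corner_strength = numeric(0), corner_sd = numeric(0)),
    chins = data.frame(center = centers, extent = extents,
                       enrichment = enrichment),
    chin_pairs = data.frame(i = integer(0), j = integer(0),
                            enrichment = numeric(0), sd = numeric(0)))
  make_truth(cfg, seed = seed)
}

test_that("kernel score: exact template, flat window, planted hairpin", {
  g <- genome_spec("chr", 10000, 100)
  n <- g$n_bins
  # counts arranged exactly like the ridge template -> correlation 1
  cfg <- detect_config(kernel_halfwidth = 8L, stem_width = 1)
  center_bin <- 50
  dense <- matrix(1, n, n)
  for (i in 1:n) for (j in i:n) {
    if (abs(i + j - 2 * center_bin) <= 1 && (j - i) <= 6 && (j - i) >= 2) {
      dense[i, j] <- 5; dense[j, i] <- 5
    }
  }
  m <- matrix_from_dense(g, dense)
  ex <- flat_expected(n, value = 1, ignore_diags = 2L)
  sc <- hairpin_kernel_score(m, ex, (center_bin - 0.5) * 100, cfg)
  expect_equal(sc, 1, tolerance = 1e-12)

  # flat window: zero variance -> no score
  m_flat <- matrix_from_dense(g, matrix(2, n, n))
  expect_true(is.na(hairpin_kernel_score(m_flat, ex, 5000, cfg)))

  # planted hairpin: strong at the apex, weak 2 kb away
  truth <- hairpin_world(3, centers = 100000, extents = 3000)
  mm <- ice_balance(sample_contact_map(truth))
  ee <- expected_by_distance(mm, ignore_diags = 2L)
  dcfg <- detect_config()
  expect_gt(hairpin_kernel_score(mm, ee, 100000, dcfg), 0.3)
  expect_lt(hairpin_kernel_score(mm, ee, 102000, dcfg), 0.3)
  expect_lt(hairpin_kernel_score(mm, ee, 98000, dcfg), 0.3)
})

test_that("detector recovers planted hairpins and is deterministic", {
  centers <- c(30000, 60000, 90000, 120000, 150000, 175000)
  extents <- c(800, 1500, 2000, 3000, 4500, 6000)
  truth <- hairpin_world(11, centers, extents)
  m <- ice_balance(sample_contact_map(truth))
  e <- expected_by_distance(m, ignore_diags = 2L)
  calls <- detect_chins(m, e)
  expect_equal(nrow(calls), 6L)
  ord <- order(calls$center)
  expect_true(all(abs(calls$center[ord] - centers) <= 200))
  rel_err <- abs(calls$extent[ord] - extents) / extents
  expect_lt(stats::median(rel_err), 0.2)
  calls2 <- detect_chins(m, e)
  expect_identical(calls, calls2)
})

test_that("no calls arise from pure decay (single-seed check)", {
  truth <- pure_decay_truth(29, genome_length = 200000, depth = 8e5)
  m <- ice_balance(sample_contact_map(truth))
  e <- expected_by_distance(m, ignore_diags = 2L)
  expect_equal(nrow(detect_chins(m, e)), 0L)
})

test_that("detector is invariant to uniform count scaling", {
  truth <- hairpin_world(7, centers = c(50000, 120000),
                         extents = c(2000, 3500))
  m_raw <- sample_contact_map(truth)
  m1 <- ice_balance(m_raw)
  m_raw2 <- m_raw
  m_raw2$counts <- m_raw$counts * 4
  m_raw2$cache <- new.env(parent = emptyenv())
  m2 <- ice_balance(m_raw2)
  e1 <- expected_by_distance(m1, 2L); e2 <- expected_by_distance(m2, 2L)
  c1 <- detect_chins(m1, e1); c2 <- detect_chins(m2, e2)
  expect_equal(c1$center, c2$center)
  expect_equal(c1$extent, c2$extent)
  expect_equal(c1$score, c2$score, tolerance = 1e-9)
})

test_that("chid clustering merges overlapping call chains", {
  cfg <- detect_config(chid_min_members = 2L, chid_max_gap = 1000)
  one <- data.frame(center = 5000, extent = 2000, score = 0.5,
                    start = 4000, end = 6000)
  expect_equal(nrow(cluster_chids(one, cfg)), 0L)

  three <- data.frame(center = c(5000, 6500, 8000),
                      extent = c(2000, 2000, 2000), score = 0.5,
                      start = c(4000, 5500, 7000), end = c(6000, 7500, 9000))
  chid <- cluster_chids(three, cfg)
  expect_equal(nrow(chid), 1L)
  expect_equal(chid$start, 4000)
  expect_equal(chid$end, 9000)
  expect_equal(chid$n_members, 3L)

  # far-apart singletons stay unclustered; order does not matter
  spread <- rbind(three, data.frame(center = 50000, extent = 2000,
                                    score = 0.4, start = 49000, end = 51000))
  chid2 <- cluster_chids(spread[sample(4), ], cfg)
  expect_equal(nrow(chid2), 1L)
})

test_that("planted hairpin domains are recovered with Jaccard >= 0.8", {
  cfg <- sim_config(genome_length = 250000, base_depth = 1e6,
                    n_htg_islands = 4, htg_island_length = 20000,
                    n_chins = 4, n_chids = 2, chid_members = 3,
                    n_chin_pairs = 0, n_operons = 10, n_opcids = 0)
  truth <- make_truth(cfg, seed = 19)
  m <- ice_balance(sample_contact_map(truth))
  e <- expected_by_distance(m, 2L)
  calls <- detect_chins(m, e)
  chids <- cluster_chids(calls)
  tf <- truth_features(truth)
  expect_equal(nrow(tf$chids), 2L)
  jacc <- vapply(seq_len(nrow(tf$chids)), function(k) {
    ts <- tf$chids$start[k]; te <- tf$chids$end[k]
    best <- 0
    for (q in seq_len(nrow(chids))) {
      inter <- max(0, min(te, chids$end[q]) - max(ts, chids$start[q]))
      uni <- max(te, chids$end[q]) - min(ts, chids$start[q])
      best <- max(best, inter / uni)
    }
    best
  }, numeric(1))
  expect_true(all(jacc >= 0.8))
})

test_that("opcid score: flat field zero, planted domain ~log(2), specificity", {
  g <- genome_spec("chr", 100000, 100)
  n <- g$n_bins
  dense <- 1 / (abs(outer(1:n, 1:n, "-")) + 1)
  m <- matrix_from_dense(g, dense)
  e <- expected_by_distance(m, 2L)
  expect_equal(opcid_score(m, e, list(start = 20000, end = 24000)), 0,
               tolerance = 1e-9)
  expect_true(is.na(opcid_score(m, e, list(start = 100, end = 300))))

  # planted 2x square domain read back at high depth under exact weights
  ops <- data.frame(start = 40000, end = 44000, strand = "+", id = "op_1",
                    activity = 0.01)
  cfg <- sim_config(
    genome_length = 100000, base_depth = 1e7, operons = ops,
    opcids = data.frame(start = 40000, end = 44000, tss = 40000, tes = 43999,
                        domain_enrichment = 2, corner_strength = 1,
                        corner_sd = 200),
    chins = data.frame(center = 20000, extent = 3000, enrichment = 3),
    chin_pairs = data.frame(i = integer(0), j = integer(0),
                            enrichment = numeric(0), sd = numeric(0)))
  truth <- make_truth(cfg, seed = 37)
  mm <- with_unit_weights(sample_contact_map(truth))
  ee <- expected_by_distance(mm, 2L)
  sc <- opcid_score(mm, ee, list(start = 40000, end = 44000))
  expect_equal(sc, log(2), tolerance = 0.1)
  # silenced hairpin-only region is not domain-like
  sc_chin <- opcid_score(mm, ee, list(start = 18500, end = 21500))
  expect_lt(sc_chin, 0.05)
})

test_that("hairpin-hairpin contact score reads back planted loops", {
  cfg <- sim_config(
    genome_length = 150000, base_depth = 3e6,
    operons = data.frame(start = 1000, end = 3000, strand = "+",
                         id = "op_1", activity = 0),
    opcids = data.frame(start = numeric(0), end = numeric(0),
                        tss = numeric(0), tes = numeric(0),
                        domain_enrichment = numeric(0),
                        corner_strength = numeric(0), corner_sd = numeric(0)),
    chins = data.frame(center = c(50000, 70000, 110000),
                       extent = c(2000, 2000, 2000), enrichment = 3),
    chin_pairs = data.frame(i = 1L, j = 2L, enrichment = 3, sd = 800))
  truth <- make_truth(cfg, seed = 41)
  m <- with_unit_weights(sample_contact_map(truth))
  e <- expected_by_distance(m, 2L)
  calls <- data.frame(start = c(49000, 69000, 109000),
                      end = c(51000, 71000, 111000))
  s12 <- chin_contact_score(m, e, calls[1, ], calls[2, ])
  s13 <- chin_contact_score(m, e, calls[1, ], calls[3, ])
  expect_gt(s12, 2)        # planted loop
  expect_equal(s13, 1, tolerance = 0.35)  # no interaction ~ 1
  expect_equal(s12, chin_contact_score(m, e, calls[2, ], calls[1, ]))
  expect_error(chin_contact_score(m, e, calls[1, ],
                                  data.frame(start = 50500, end = 52000)),
               "overlap")
})
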