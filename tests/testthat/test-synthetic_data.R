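test_that("truths are deterministic and validated", {
  cfg <- sim_config(genome_length = 150000, base_depth = 5e5,
                    n_htg_islands = 3, htg_island_length = 15000,
                    n_chins = 5, n_chids = 1, n_operons = 15, n_opcids = 6)
  t1 <- make_truth(cfg, seed = 5)
  t2 <- make_truth(cfg, seed = 5)
  expect_identical(t1$chins, t2$chins)
  expect_identical(t1$operons, t2$operons)
  expect_identical(t1$opcids, t2$opcids)
  t3 <- make_truth(cfg, seed = 6)
  expect_false(identical(t1$chins, t3$chins))

  # every hairpin lies inside an HTG island
  for (k in seq_len(nrow(t1$chins))) {
    lo <- t1$chins$center[k] - t1$chins$extent[k] / 2
    hi <- t1$chins$center[k] + t1$chins$extent[k] / 2
    expect_true(any(lo >= t1$htg_islands$start & hi <= t1$htg_islands$end))
  }
  # hairpins outside islands are rejected
  expect_error(
    sim_truth(t1$genome, 1.1, 1e5, t1$operons, t1$opcids,
              data.frame(center = 1000, extent = 500, enrichment = 3,
                         stem_width = 2, chid = 0L),
              t1$chin_pairs, t1$htg_islands, 200, 1),
    "island")
})

test_that("hairpin extents follow the stated lognormal around 2 kb", {
  cfg <- sim_config(genome_length = 2000000, n_htg_islands = 25L,
                    n_chins = 50L, n_chids = 0L, n_operons = 20L,
                    n_chin_pairs = 0L)
  truth <- make_truth(cfg, seed = 8)
  expect_equal(nrow(truth$chins), 50L)
  med <- stats::median(truth$chins$extent)
  expect_gt(med, 1500); expect_lt(med, 2700)
  expect_true(all(truth$chins$extent >= 500 & truth$chins$extent <= 6000))
})

test_that("intensity model: pure decay slope, hairpin ratio, normalization", {
  truth0 <- pure_decay_truth(1, genome_length = 50000, depth = 1e5)
  em0 <- expected_map_from_truth(truth0)
  lam <- vapply(1:400, function(d) lambda_diag(em0, d)[1], numeric(1))
  slope <- stats::coef(stats::lm(log(lam) ~ log(1:400)))[2]
  expect_equal(unname(slope), -1.1, tolerance = 1e-9)

  # hairpin enrichment is exactly multiplicative on the anti-diagonal
  g <- genome_spec("sim", 50000, 100)
  chin <- data.frame(center = 25000, extent = 3000, enrichment = 3,
                     stem_width = 2, chid = 0L)
  truth <- truth0
  truth$chins <- chin
  truth$htg_islands <- genomic_intervals(20000, 30000)
  em <- expected_map_from_truth(truth)
  d <- 10L
  lam_d <- lambda_diag(em, d)
  cb <- 25000 / 100
  on_ridge <- round(cb + (1 - d) / 2)
  expect_equal(lam_d[on_ridge] / lam_d[100], 3, tolerance = 1e-9)

  # upper-triangle integral equals base_depth
  tot <- 0
  for (dd in 0:(em$n - 1)) tot <- tot + sum(lambda_diag(em, dd))
  expect_equal(tot, truth$base_depth, tolerance = 1e-9 * truth$base_depth)
})

test_that("contact sampling is seeded Poisson with the right margins", {
  truth <- pure_decay_truth(3, genome_length = 50000, depth = 1e6)
  em <- expected_map_from_truth(truth)
  m1 <- sample_contact_map(truth, em)
  m2 <- sample_contact_map(truth, em)
  expect_identical(m1$counts, m2$counts)
  expect_lt(abs(total_contacts(m1) - truth$base_depth),
            4 * sqrt(truth$base_depth))

  # per-diagonal means match lambda within 3 SE
  z <- vapply(c(1, 5, 20, 100, 300), function(d) {
    lam <- lambda_diag(em, d)
    obs <- sum(m1$counts[cbind(seq_along(lam), seq_along(lam) + d)])
    (obs - sum(lam)) / sqrt(sum(lam))
  }, numeric(1))
  expect_true(all(abs(z) < 3))

  # zero depth -> empty matrix
  t0 <- pure_decay_truth(4, genome_length = 20000, depth = 0)
  expect_equal(total_contacts(sample_contact_map(t0)), 0)
})

test_that("Red-C simulation: rates, proximity mass, determinism", {
  cfg <- sim_config(genome_length = 300000, base_depth = 1e5,
                    n_htg_islands = 3, htg_island_length = 15000,
                    n_chins = 3, n_chids = 0, n_operons = 40, n_opcids = 10,
                    redc_depth = 3e4)
  truth <- make_truth(cfg, seed = 9)
  rc <- simulate_redc(truth)
  rc2 <- simulate_redc(truth)
  expect_identical(rc, rc2)
  expect_gt(mean(abs(rc$rna_pos - rc$dna_pos) <= 10000), 0.85)
  expect_lt(abs(nrow(rc) - 3e4) / 3e4, 0.1)

  ann <- annotate_operon_activity(truth$operons, rc)
  act <- truth$operons$activity
  expect_gt(stats::cor(act, ann$redc_signal, method = "spearman"), 0.85)
  expect_true(all(ann$redc_signal[act == 0] <=
                    stats::quantile(ann$redc_signal[act > 0], 0.6)))

  # all-zero rates -> no contacts
  t0 <- truth
  t0$operons$activity <- 0
  expect_equal(nrow(simulate_redc(t0)), 0L)
})

test_that("ChIP-like tracks show the planted phenotypes", {
  cfg <- sim_config(genome_length = 200000, base_depth = 1e5,
                    n_htg_islands = 3, htg_island_length = 15000,
                    n_chins = 6, n_chids = 0, n_operons = 25, n_opcids = 8)
  truth <- make_truth(cfg, seed = 15)
  hns <- simulate_chip_track(truth, "hns_like")
  expect_identical(hns$values, simulate_chip_track(truth, "hns_like")$values)

  # no hairpins -> flat noise floor
  t0 <- truth; t0$chins <- truth$chins[0, ]
  flat <- simulate_chip_track(t0, "hns_like", noise_floor = 2)
  expect_lt(mean(flat$values), 3)
  expect_lt(stats::sd(flat$values), 3)

  # rnap-like: top-activity operons >> silent operons
  rnap <- simulate_chip_track(truth, "rnap_like")
  ops <- truth$operons
  bin_mean <- function(op) {
    b <- (floor(op$start / 100) + 1):ceiling(op$end / 100)
    mean(rnap$values[b])
  }
  act <- ops$activity
  top <- which(act >= stats::quantile(act[act > 0], 0.9))
  zero <- which(act == 0)
  mu_top <- mean(vapply(top, function(k) bin_mean(ops[k, ]), numeric(1)))
  mu_zero <- mean(vapply(zero, function(k) bin_mean(ops[k, ]), numeric(1)))
  expect_gt(mu_top / mu_zero, 5)
})

test_that("truth JSON round-trips", {
  cfg <- sim_config(genome_length = 150000, base_depth = 4e5,
                    n_htg_islands = 3, htg_island_length = 15000,
                    n_chins = 4, n_chids = 1, n_operons = 12, n_opcids = 5)
  truth <- make_truth(cfg, seed = 22)
  tp <- withr::local_tempfile(fileext = ".json")
  write_truth(truth, tp)
  back <- read_truth(tp)
  expect_equal(back$chins$center, truth$chins$center)
  expect_equal(back$operons$activity, truth$operons$activity)
  expect_equal(back$seeds$contacts, truth$seeds$contacts)
  m1 <- sample_contact_map(truth)
  m2 <- sample_contact_map(back)
  expect_identical(m1$counts, m2$counts)
})
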