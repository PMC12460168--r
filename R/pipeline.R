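# End-to-end pipeline: simulate/load -> balance -> expected -> scaling ->
# detect -> statistics, with a manifest so a run is reproducible from its
# config alone. All outputs are plain text (TSV/JSON/BED/bedGraph).

#' Default pipeline configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global seed; stage seeds are derived from it.
#' @param simulate A [sim_config()] (used when no `inputs` are given).
#' @param inputs Optional named list of file paths: `contacts` (COO TSV
#'   written by [write_contacts()]), `operons` (TSV), `redc` (TSV),
#'   `shuffle_b` (BED of B-intervals for the shuffle stage).
#' @param stages Named logical list toggling `balance`, `expected`,
#'   `scaling`, `detect`, `tss_tes`, `shuffle`, `redc_profile`.
#' @param ignore_diags Expected-model ignored diagonals (default 2).
#' @param endpoint An [endpoint_config()].
#' @param shuffle A [shuffle_config()].
#' @param detect A [detect_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = sim_config(),
                       inputs = NULL,
                       stages = list(balance = TRUE, expected = TRUE,
                                     scaling = TRUE, detect = TRUE,
                                     tss_tes = TRUE, shuffle = TRUE,
                                     redc_profile = TRUE),
                       ignore_diags = 2L,
                       endpoint = endpoint_config(window_bp = 400),
                       shuffle = shuffle_config(),
                       detect = detect_config()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, stages = stages,
                 ignore_diags = as.integer(ignore_diags),
                 endpoint = endpoint, shuffle = shuffle, detect = detect),
            class = "run_config")
}

stage_on <- function(cfg, name) isTRUE(cfg$stages[[name]])

require_stage <- function(cfg, name, needed_by) {
  if (!stage_on(cfg, name)) {
    stop(sprintf("stage '%s' requires stage '%s' to be enabled",
                 needed_by, name))
  }
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and writes all outputs
#' plus a `manifest.json` (inputs, seeds, parameters, stage log) under
#' `cfg$out_dir`. With no `inputs`, a synthetic nucleoid is simulated
#' first and its ground truth is written alongside the analysis outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage products
#'   (`matrix`, `expected`, `chins`, `chids`, `stats`, `shuffle`, ...).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[pipeline] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  out <- list()
  p <- function(...) file.path(cfg$out_dir, ...)

  operons <- NULL; redc <- NULL; shuffle_b <- NULL
  if (is.null(cfg$inputs)) {
    note("simulating synthetic nucleoid (seed %d)", cfg$seed)
    truth <- make_truth(cfg$simulate, seed = cfg$seed)
    em <- expected_map_from_truth(truth)
    m <- sample_contact_map(truth, em)
    redc <- simulate_redc(truth)
    hns <- simulate_chip_track(truth, "hns_like")
    tf <- truth_features(truth)
    write_truth(truth, p("truth.json"))
    write_genome_spec(truth$genome, p("genome.json"))
    write_contacts(m, p("contacts.coo.tsv"))
    write_redc(redc, p("redc.tsv"))
    write_bedgraph(hns, p("hns_like.bedgraph"), chrom = truth$genome$name)
    write_bed(tf$chins, p("truth_chins.bed"), chrom = truth$genome$name)
    write_bed(tf$chids, p("truth_chids.bed"), chrom = truth$genome$name)
    write_bed(tf$opcids, p("truth_opcids.bed"), chrom = truth$genome$name)
    write_bed(tf$htg_islands, p("truth_htgs.bed"), chrom = truth$genome$name)
    operons <- truth$operons
    shuffle_b <- tf$htg_islands
    out$truth <- truth
  } else {
    note("loading contacts from %s", cfg$inputs$contacts)
    m <- read_contacts(cfg$inputs$contacts)
    if (!is.null(cfg$inputs$operons)) operons <- read_operons(cfg$inputs$operons, m$genome)
    if (!is.null(cfg$inputs$redc)) redc <- read_redc(cfg$inputs$redc, m$genome)
    if (!is.null(cfg$inputs$shuffle_b)) shuffle_b <- read_bed(cfg$inputs$shuffle_b, m$genome)
  }
  genome <- m$genome

  if (stage_on(cfg, "balance")) {
    m <- ice_balance(m)
    note("balanced: %d iterations, CV %.2e, %d masked bins",
         m$balancing$iterations, m$balancing$cv, m$balancing$n_masked)
    write_contacts(m, p("balanced.coo.tsv"))
  }
  out$matrix <- m

  expected <- NULL
  if (stage_on(cfg, "expected")) {
    require_stage(cfg, "balance", "expected")
    expected <- expected_by_distance(m, ignore_diags = cfg$ignore_diags)
    data.table::fwrite(data.table::as.data.table(expected),
                       p("expected.tsv"), sep = "\t")
  }
  out$expected <- expected

  if (stage_on(cfg, "scaling")) {
    sc <- scaling_curve(m)
    data.table::fwrite(data.table::as.data.table(sc), p("scaling.tsv"),
                       sep = "\t")
    out$scaling <- sc
  }

  if (stage_on(cfg, "detect")) {
    require_stage(cfg, "expected", "detect")
    chins <- detect_chins(m, expected, cfg$detect)
    chids <- cluster_chids(chins, cfg$detect)
    note("detected %d hairpins, %d hairpin domains", nrow(chins), nrow(chids))
    write_chin_calls(chins, bed_path = p("chins.bed"),
                     tsv_path = p("chins.tsv"), chrom = genome$name)
    write_bed(chids, p("chids.bed"), chrom = genome$name)
    out$chins <- chins; out$chids <- chids
    if (!is.null(operons)) {
      osc <- vapply(seq_len(nrow(operons)), function(k) {
        opcid_score(m, expected, operons[k, , drop = FALSE])
      }, numeric(1))
      data.table::fwrite(data.table::data.table(id = operons$id,
                                                opcid_score = osc),
                         p("opcid_scores.tsv"), sep = "\t")
      out$opcid_scores <- osc
    }
  }

  if (stage_on(cfg, "tss_tes")) {
    require_stage(cfg, "expected", "tss_tes")
    if (is.null(operons)) stop("tss_tes stage needs an operon table")
    if (!is.null(redc)) operons <- annotate_operon_activity(operons, redc)
    if (all(is.na(operons$redc_signal))) {
      stop("tss_tes stage needs Red-C contacts or pre-annotated operons")
    }
    stats <- operon_contact_stats(m, operons, cfg$endpoint)
    grouped <- group_operons_by_activity(operons, "fig2g")
    stats$group <- grouped$group[match(stats$id, grouped$id)]
    data.table::fwrite(data.table::as.data.table(stats),
                       p("tss_tes_stats.tsv"), sep = "\t")
    summ <- summarize_contact_groups(stats[!is.na(stats$group), ])
    data.table::fwrite(data.table::as.data.table(summ),
                       p("tss_tes_groups.tsv"), sep = "\t")
    out$stats <- stats; out$group_summary <- summ
  }

  if (stage_on(cfg, "shuffle")) {
    require_stage(cfg, "detect", "shuffle")
    if (!is.null(shuffle_b) && nrow(out$chins)) {
      a_iv <- genomic_intervals(out$chins$start, out$chins$end, genome = genome)
      sh <- shuffle_test(a_iv, shuffle_b, genome, cfg$shuffle)
      write_shuffle_result(sh, p("shuffle_result.json"),
                           null_tsv = p("shuffle_null.tsv"))
      note("shuffle test: observed %d, p = %.4g (%s)", sh$observed,
           sh$p_two_sided, sh$direction)
      out$shuffle <- sh
    } else {
      note("shuffle stage skipped: no B intervals or no hairpin calls")
    }
  }

  if (stage_on(cfg, "redc_profile") && !is.null(redc)) {
    prof <- redc_profile(redc, genome,
                         redc_config(bin_size = genome$resolution))
    write_bedgraph(prof, p("redc_profile.bedgraph"), chrom = genome$name)
    out$redc_profile <- prof
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("nucleoidC")),
    seed = cfg$seed,
    inputs = cfg$inputs,
    stages = cfg$stages,
    parameters = list(ignore_diags = cfg$ignore_diags,
                      endpoint = unclass(cfg$endpoint),
                      shuffle = unclass(cfg$shuffle),
                      detect = unclass(cfg$detect),
                      simulate = if (is.null(cfg$inputs))
                        unclass(cfg$simulate)[!vapply(cfg$simulate, is.data.frame, logical(1))]
                      else NULL),
    log = log_lines
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(out)
}
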