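# Transcription-activity estimation from RNA-DNA (Red-C) contacts.
#
# The activity of a feature is the number of contacts whose RNA read maps
# inside the feature and whose DNA read maps within max_dist of the RNA
# read (the "near the parental locus" rule). Coordinates are single bp
# positions (the read's reported mapping coordinate); the distance
# threshold is inclusive.

#' Red-C configuration
#'
#' @param max_dist Maximum RNA-DNA mapping distance in bp, inclusive
#'   (default 10,000).
#' @param bin_size Bin width in bp for genome-wide profiles (default 100).
#' @return A list of class `redc_config`.
#' @export
redc_config <- function(max_dist = 10000, bin_size = 100) {
  stopifnot(max_dist > 0, bin_size > 0)
  structure(list(max_dist = max_dist, bin_size = bin_size),
            class = "redc_config")
}

#' Construct / read / write Red-C contact tables
#'
#' A contact is a pair of mapped coordinates (`rna_pos`, `dna_pos`, both
#' 0-based bp) with an optional `multiplicity` count (default 1). The TSV
#' format is tab-separated with a header.
#'
#' @param rna_pos,dna_pos Numeric positions in bp.
#' @param multiplicity Positive integer counts.
#' @param genome Optional `genome_spec` for bounds checking.
#' @return A data.frame of class `redc_contacts`.
#' @export
redc_contacts <- function(rna_pos, dna_pos, multiplicity = 1, genome = NULL) {
  rna_pos <- as.numeric(rna_pos); dna_pos <- as.numeric(dna_pos)
  multiplicity <- rep_len(as.numeric(multiplicity), length(rna_pos))
  if (length(rna_pos) != length(dna_pos)) stop("rna_pos/dna_pos lengths differ")
  if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
  if (!is.null(genome)) {
    if (length(rna_pos) && (min(rna_pos, dna_pos) < 0 ||
                            max(rna_pos, dna_pos) >= genome$length)) {
      stop("Red-C position outside genome")
    }
  }
  structure(data.frame(rna_pos = rna_pos, dna_pos = dna_pos,
                       multiplicity = multiplicity),
            class = c("redc_contacts", "data.frame"))
}

#' @param path TSV path.
#' @rdname redc_contacts
#' @export
read_redc <- function(path, genome = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("rna_pos", "dna_pos") %in% names(dt))) {
    stop("Red-C TSV needs columns rna_pos, dna_pos[, multiplicity]")
  }
  redc_contacts(dt$rna_pos, dt$dna_pos,
                if ("multiplicity" %in% names(dt)) dt$multiplicity else 1,
                genome = genome)
}

#' @param contacts A `redc_contacts` table.
#' @rdname redc_contacts
#' @export
write_redc <- function(contacts, path) {
  data.table::fwrite(data.table::as.data.table(contacts), path, sep = "\t")
  invisible(path)
}

#' Red-C signal of one feature
#'
#' Total multiplicity of contacts with `rna_pos` inside `[start, end)` of
#' the feature and `|rna_pos - dna_pos| <= max_dist`.
#'
#' @param contacts A `redc_contacts` table.
#' @param feature A one-row interval (list or data.frame with `start`, `end`).
#' @param cfg A [redc_config()].
#' @return Named numeric vector `c(signal=, density=)` with
#'   `density = signal / length`.
#' @export
feature_redc_signal <- function(contacts, feature, cfg = redc_config()) {
  s <- as.numeric(feature$start)[1]; e <- as.numeric(feature$end)[1]
  if (!(s < e)) stop("degenerate feature")
  sel <- contacts$rna_pos >= s & contacts$rna_pos < e &
    abs(contacts$rna_pos - contacts$dna_pos) <= cfg$max_dist
  sig <- sum(contacts$multiplicity[sel])
  c(signal = sig, density = sig / (e - s))
}

#' Genome-wide per-bin Red-C transcription profile
#'
#' For each bin, the number of contacts whose RNA maps in the bin and whose
#' DNA maps within `max_dist` of the RNA (the same proximity rule as
#' [feature_redc_signal()] with the bin as the feature).
#'
#' @param contacts A `redc_contacts` table.
#' @param genome A `genome_spec`.
#' @param cfg A [redc_config()]; `bin_size` sets the profile resolution.
#' @return A [signal_track()] of per-bin counts.
#' @export
redc_profile <- function(contacts, genome, cfg = redc_config()) {
  n <- as.integer(ceiling(genome$length / cfg$bin_size))
  near <- abs(contacts$rna_pos - contacts$dna_pos) <= cfg$max_dist
  vals <- numeric(n)
  if (any(near)) {
    bins <- floor(contacts$rna_pos[near] / cfg$bin_size) + 1L
    agg <- rowsum(contacts$multiplicity[near], bins)
    vals[as.integer(rownames(agg))] <- agg[, 1]
  }
  signal_track(vals, cfg$bin_size)
}

#' Annotate operon activity from Red-C contacts
#'
#' Fills `redc_signal` and `redc_density` for every operon using
#' [feature_redc_signal()].
#'
#' @param operons An `operon_table`.
#' @param contacts A `redc_contacts` table.
#' @param cfg A [redc_config()].
#' @return The operon table with activity columns filled.
#' @export
annotate_operon_activity <- function(operons, contacts, cfg = redc_config()) {
  near <- abs(contacts$rna_pos - contacts$dna_pos) <= cfg$max_dist
  rna <- contacts$rna_pos[near]; mult <- contacts$multiplicity[near]
  sig <- vapply(seq_len(nrow(operons)), function(f) {
    sum(mult[rna >= operons$start[f] & rna < operons$end[f]])
  }, numeric(1))
  operons$redc_signal <- sig
  operons$redc_density <- sig / (operons$end - operons$start)
  operons
}
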