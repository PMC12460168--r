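#' Genome specification for a single bacterial chromosome
#'
#' All coordinates in this package live on one circular bacterial replicon
#' (the reference model is the 4,641,652 bp *E. coli* K-12 chromosome).
#' A `genome_spec` fixes the chromosome name, its length, circularity and
#' the bin size (resolution) used for contact matrices. Distances are
#' treated linearly (no wrap across the origin) throughout, matching the
#' conventions of the standard contact-map tool stack; circularity is
#' carried as metadata only.
#'
#' @param name Chromosome name (single string). All interval files must use
#'   this name (or omit names entirely).
#' @param length Chromosome length in bp (> 0).
#' @param resolution Bin size in bp; 10 bp is the finest supported.
#' @param circular Logical; metadata only (distances stay linear).
#'
#' @return An object of class `genome_spec` with fields `name`, `length`,
#'   `circular`, `resolution` and the derived `n_bins = ceiling(length/resolution)`.
#' @examples
#' g <- genome_spec("chr", 500000, resolution = 100)
#' g$n_bins
#' @export
genome_spec <- function(name, length, resolution, circular = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0)
  length <- as.numeric(length)
  resolution <- as.numeric(resolution)
  if (!is.finite(length) || length <= 0) stop("genome length must be > 0")
  if (!is.finite(resolution) || resolution < 10) {
    stop("resolution must be an integer >= 10 bp")
  }
  if (resolution != round(resolution)) stop("resolution must be an integer number of bp")
  structure(
    list(
      name = name,
      length = length,
      circular = isTRUE(circular),
      resolution = resolution,
      n_bins = as.integer(ceiling(length / resolution))
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_spec> %s: %s bp (%s), %d bp bins, %d bins\n",
    x$name, format(x$length, big.mark = ","),
    if (x$circular) "circular" else "linear",
    as.integer(x$resolution), x$n_bins
  ))
  invisible(x)
}

#' Read / write a genome specification as JSON
#'
#' @param path File path.
#' @return `read_genome_spec` returns a `genome_spec`.
#' @rdname genome_spec_io
#' @export
read_genome_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  genome_spec(j$name, j$length, j$resolution, isTRUE(j$circular))
}

#' @param genome A `genome_spec`.
#' @rdname genome_spec_io
#' @export
write_genome_spec <- function(genome, path) {
  stopifnot(inherits(genome, "genome_spec"))
  jsonlite::write_json(
    list(name = genome$name, length = genome$length,
         resolution = genome$resolution, circular = genome$circular),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Construct and validate a table of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, the BED convention, on a
#' single chromosome. Strand is one of `+`, `-` or `.` (unstranded).
#'
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @param id Optional character ids (auto-generated when missing).
#' @param strand Strand vector (recycled), each `+`, `-` or `.`.
#' @param genome Optional `genome_spec`; when given, intervals must lie
#'   within `[0, genome$length]`.
#' @return A `data.frame` with columns `start`, `end`, `id`, `strand` and
#'   class `genomic_intervals`.
#' @export
genomic_intervals <- function(start, end, id = NULL, strand = ".", genome = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start and end lengths differ")
  if (is.null(id)) id <- if (length(start)) sprintf("iv_%d", seq_along(start)) else character(0)
  strand <- rep_len(as.character(strand), length(start))
  df <- data.frame(start = start, end = end, id = as.character(id),
                   strand = strand, stringsAsFactors = FALSE)
  validate_intervals(df, genome)
}

#' @param x A data.frame with at least `start` and `end` columns.
#' @rdname genomic_intervals
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  if (nrow(x)) {
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad)) {
      stop(sprintf("invalid interval(s) at row %s: need 0 <= start < end", bad[1]))
    }
    if (!is.null(genome) && any(x$end > genome$length)) {
      stop("interval end beyond genome length")
    }
    if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "."))) {
      stop("strand must be one of '+', '-', '.'")
    }
  }
  if (is.null(x$id)) x$id <- if (nrow(x)) sprintf("iv_%d", seq_len(nrow(x))) else character(0)
  if (is.null(x$strand)) x$strand <- rep(".", nrow(x))
  class(x) <- unique(c("genomic_intervals", class(x)))
  x
}

interval_lengths <- function(x) x$end - x$start

#' Median interval length
#'
#' Median of `end - start`; for even counts, the mean of the two central
#' values (the usual sample median).
#'
#' @param intervals A `genomic_intervals` table (or any data.frame with
#'   `start`/`end`).
#' @return Median length in bp.
#' @export
median_length <- function(intervals) {
  if (!is.data.frame(intervals) || nrow(intervals) == 0) {
    stop("median_length: empty interval list")
  }
  stats::median(interval_lengths(intervals))
}

# ---- operons ----------------------------------------------------------------

#' Construct an operon table
#'
#' An operon is an oriented transcription unit. Internally its coordinates
#' are 0-based half-open; the oriented endpoints are derived from strand:
#' on `+` the TSS is `start` and the TES is `end - 1`; on `-` they swap.
#' `redc_density` is maintained as `redc_signal / length` exactly.
#'
#' @param start,end 0-based half-open coordinates.
#' @param strand `+` or `-` per operon (unstranded operons are not allowed).
#' @param id Optional ids.
#' @param sigma Optional sigma-factor label (e.g. "sigma70", "sigma32").
#' @param redc_signal Non-negative RNA-DNA contact counts (transcription
#'   activity proxy); defaults to `NA` until annotated.
#' @param genome Optional `genome_spec` for bounds checking.
#' @return A `data.frame` of class `operon_table` with columns `id`,
#'   `start`, `end`, `strand`, `sigma`, `redc_signal`, `redc_density`,
#'   `tss`, `tes`.
#' @export
operon_table <- function(start, end, strand, id = NULL, sigma = NA_character_,
                         redc_signal = NA_real_, genome = NULL) {
  iv <- genomic_intervals(start, end, id = id, strand = strand, genome = genome)
  if (nrow(iv) && any(iv$strand == ".")) stop("unstranded operon")
  x <- data.frame(
    id = iv$id, start = iv$start, end = iv$end, strand = iv$strand,
    sigma = rep_len(as.character(sigma), nrow(iv)),
    redc_signal = rep_len(as.numeric(redc_signal), nrow(iv)),
    stringsAsFactors = FALSE
  )
  if (nrow(x) && any(!is.na(x$redc_signal) & x$redc_signal < 0)) {
    stop("redc_signal must be non-negative")
  }
  x$redc_density <- x$redc_signal / (x$end - x$start)
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1)
  x$tes <- ifelse(x$strand == "+", x$end - 1, x$start)
  class(x) <- unique(c("operon_table", "genomic_intervals", class(x)))
  x
}

#' Oriented promoter and terminator coordinates of one operon
#'
#' @param operon A single-row slice of an `operon_table` (or a list with
#'   `start`, `end`, `strand`).
#' @return Named numeric vector `c(tss=, tes=)`; the TSS precedes the TES
#'   in the direction of transcription.
#' @examples
#' op <- operon_table(100, 600, "+")
#' endpoints_of(op[1, ])
#' @export
endpoints_of <- function(operon) {
  strand <- as.character(operon$strand)[1]
  if (is.na(strand) || !strand %in% c("+", "-")) stop("unstranded operon")
  s <- as.numeric(operon$start)[1]; e <- as.numeric(operon$end)[1]
  if (strand == "+") c(tss = s, tes = e - 1) else c(tss = e - 1, tes = s)
}

# ---- readers / writers ------------------------------------------------------

#' Read / write BED interval files
#'
#' BED is native to the internal convention (0-based half-open). BED3
#' (no ids/strand) and BED6 are supported; a chromosome name column must be
#' constant and, when a genome is given, equal to `genome$name`.
#'
#' @param path BED file path.
#' @param genome Optional `genome_spec` for validation.
#' @return `read_bed` returns a `genomic_intervals` table.
#' @rdname bed_io
#' @export
read_bed <- function(path, genome = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("BED needs at least 3 columns")
  chrom <- unique(as.character(dt[[1]]))
  if (length(chrom) > 1) stop("multi-chromosome BED not supported")
  if (!is.null(genome) && length(chrom) == 1 && chrom != genome$name) {
    stop(sprintf("BED chromosome '%s' does not match genome '%s'", chrom, genome$name))
  }
  genomic_intervals(
    start = dt[[2]], end = dt[[3]],
    id = if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL,
    strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
    genome = genome
  )
}

#' @param intervals A `genomic_intervals` table.
#' @param chrom Chromosome name to write (defaults to "chr").
#' @rdname bed_io
#' @export
write_bed <- function(intervals, path, chrom = "chr") {
  intervals <- validate_intervals(intervals)
  dt <- data.table::data.table(
    chrom = chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    id = intervals$id,
    score = 0L,
    strand = intervals$strand
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the operon TSV format
#'
#' Tab-separated with header columns `id, start, end, strand, sigma,
#' redc_signal`. Files carrying the pragma line `#coords=1-based-inclusive`
#' (the RegulonDB-style convention) are converted to the internal 0-based
#' half-open convention on read; files without the pragma are taken as
#' already 0-based half-open. `write_operons` always writes 0-based
#' half-open without a pragma, so write -> read round-trips bit-exactly.
#'
#' @param path TSV path.
#' @param genome Optional `genome_spec`.
#' @return `read_operons` returns an `operon_table`.
#' @rdname operon_io
#' @export
read_operons <- function(path, genome = NULL) {
  first <- readLines(path, n = 1L)
  one_based <- grepl("^#\\s*coords\\s*=\\s*1-based-inclusive", first)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          skip = if (one_based) 1L else 0L)
  need <- c("id", "start", "end", "strand")
  if (!all(need %in% names(dt))) {
    stop("operon TSV must have header columns id, start, end, strand")
  }
  start <- as.numeric(dt$start); end <- as.numeric(dt$end)
  if (one_based) { start <- start - 1 }  # [s, e] 1-based inclusive -> [s-1, e) 0-based
  operon_table(
    start, end, as.character(dt$strand), id = as.character(dt$id),
    sigma = if ("sigma" %in% names(dt)) as.character(dt$sigma) else NA_character_,
    redc_signal = if ("redc_signal" %in% names(dt)) as.numeric(dt$redc_signal) else NA_real_,
    genome = genome
  )
}

#' @param operons An `operon_table`.
#' @rdname operon_io
#' @export
write_operons <- function(operons, path) {
  dt <- data.table::as.data.table(
    operons[, c("id", "start", "end", "strand", "sigma", "redc_signal")]
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Convert intervals to an IRanges object (internal helper)
#' @noRd
as_iranges <- function(intervals) {
  IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
}
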