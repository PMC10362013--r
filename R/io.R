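#' Read and write event tables
#'
#' Event tables are CSV with columns `cell_id`, `sample_id`, `slide_id`,
#' `cohort`, the channel intensity columns, and any number of morphometric
#' feature columns. Writing then reading a table reproduces it (numeric
#' values to full double precision).
#'
#' @param path File path.
#' @param events Event data frame.
#' @return `read_events()`: data frame. `write_events()`: `path`, invisibly.
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path, sep = ","),
                      stringsAsFactors = FALSE)
  need <- c("cell_id", "sample_id")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("events file missing column(s): ", paste(miss, collapse = ", "))
  }
  ev
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  data.table::fwrite(events, path, sep = ",")
  invisible(path)
}

#' Read and write bin-count tables
#'
#' Bin counts are TSV with columns `cell_id`, `chrom`, `start`, `end`,
#' `count`; coordinates are 0-based half-open. Malformed rows (non-numeric
#' fields, `end <= start`, negative counts) raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @param bin_counts Bin-count data frame.
#' @return `read_bin_counts()`: data frame. `write_bin_counts()`: `path`.
#' @export
read_bin_counts <- function(path) {
  bc <- as.data.frame(data.table::fread(path, sep = "\t"),
                      stringsAsFactors = FALSE)
  need <- c("cell_id", "chrom", "start", "end", "count")
  miss <- setdiff(need, names(bc))
  if (length(miss)) {
    stop("bin-count file missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(bc$start) | !is.finite(bc$end) |
                 !is.finite(bc$count) | bc$end <= bc$start | bc$count < 0)
  if (length(bad)) {
    stop(sprintf("malformed bin row at line %d of %s (end <= start, negative, or non-numeric)",
                 bad[1] + 1L, path))  # +1 for the header line
  }
  bc
}

#' @rdname read_bin_counts
#' @export
write_bin_counts <- function(bin_counts, path) {
  data.table::fwrite(bin_counts, path, sep = "\t")
  invisible(path)
}

#' Write and read SEG files
#'
#' Standard tab-delimited SEG dialect: `ID`, `chrom`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean`, with 1-based inclusive coordinates
#' and `seg.mean = log2(mean ratio)`. Zero mean ratios are floored at
#' `2^-10` before taking logs.
#'
#' @param profiles A `cn_profile` or list of them.
#' @param path File path.
#' @return `write_seg()`: `path`, invisibly. `read_seg()`: data frame.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    segs <- p$segments
    bins <- p$bins
    idx <- stats::ave(seq_len(nrow(bins)), bins$chrom, FUN = seq_along)
    loc <- function(ch, b, col) {
      sel <- bins$chrom == ch
      bins[[col]][sel][match(b, idx[sel])]
    }
    data.frame(
      ID = p$cell_id,
      chrom = segs$chrom,
      loc.start = vapply(seq_len(nrow(segs)), function(i)
        loc(segs$chrom[i], segs$start_bin[i], "start"), numeric(1)) + 1,
      loc.end = vapply(seq_len(nrow(segs)), function(i)
        loc(segs$chrom[i], segs$end_bin[i], "end"), numeric(1)),
      num.mark = segs$n_bins,
      seg.mean = log2(pmax(segs$mean_ratio, 2^-10)),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  seg <- as.data.frame(data.table::fread(path, sep = "\t"),
                       stringsAsFactors = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  miss <- setdiff(need, names(seg))
  if (length(miss)) {
    stop("SEG file missing column(s): ", paste(miss, collapse = ", "))
  }
  seg
}

#' Write alterations as BED
#'
#' BED with 0-based half-open coordinates, `name` = direction
#' (`gain`/`loss`), `score` = integer copy number. Bin indices are converted
#' through the profile's bin table when given, else emitted directly.
#'
#' @param alterations [extract_alterations()] output.
#' @param path File path.
#' @param bins Optional bin table (`chrom`, `start`, `end`) to map bin
#'   indices to genomic coordinates.
#' @return `path`, invisibly.
#' @export
write_alterations_bed <- function(alterations, path, bins = NULL) {
  a <- alterations
  if (!is.null(bins)) {
    idx <- stats::ave(seq_len(nrow(bins)), bins$chrom, FUN = seq_along)
    coord <- function(ch, b, col) {
      sel <- bins$chrom == ch
      bins[[col]][sel][match(b, idx[sel])]
    }
    start <- vapply(seq_len(nrow(a)), function(i)
      coord(a$chrom[i], a$start_bin[i], "start"), numeric(1))
    end <- vapply(seq_len(nrow(a)), function(i)
      coord(a$chrom[i], a$end_bin[i], "end"), numeric(1))
  } else {
    start <- a$start_bin - 1L
    end <- a$end_bin
  }
  bed <- data.frame(chrom = a$chrom, start = start, end = end,
                    name = a$direction, score = a$cn,
                    stringsAsFactors = FALSE)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML configuration with a `seed`, file paths, and per-module parameter
#' blocks (`gates`, `stratifier`, `cna`, `model`). Unknown top-level keys
#' are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "paths", "gates", "stratifier", "cna", "model",
               "cohort", "genome")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

#' Write a machine-readable JSON report
#'
#' Serializes a result list to JSON, stamping it with the seed and a hash of
#' the configuration so runs are attributable. Infinite values are encoded
#' as the string `"Inf"`.
#'
#' @param x List of results.
#' @param path Output path.
#' @param seed Seed the run used.
#' @param config Configuration list (hashed into the report).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NA_integer_, config = list()) {
  x$seed <- seed
  x$config_hash <- rlang::hash(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
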