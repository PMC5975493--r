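# TSV / BED dialects shared by the simulator and the calling pipeline.
# Matrices: first column = probe_id, remaining columns = sample ids, missing
# encoded as "NA". BED: 0-based half-open, optional name column.

#' Read a methylation beta matrix from TSV
#'
#' @param path TSV file; header row of sample ids, first column probe ids,
#'   missing values encoded as \code{NA}. Gzip input is handled transparently.
#' @return numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE, check.names = FALSE)
  if (ncol(dt) < 2) stopf("matrix %s has no sample columns", path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    stopf("duplicate probe ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1], is.numeric, logical(1)))[1]
    stopf("non-numeric cells in %s (sample column '%s')", path,
          colnames(dt)[bad + 1])
  }
  rownames(m) <- ids
  validate_betas(m)
  m
}

validate_betas <- function(m) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("beta value out of [0,1] at probe '%s', sample '%s' (value %.4g)",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
          m[bad[1, 1], bad[1, 2]])
  }
  invisible(m)
}

#' Write a beta matrix as TSV
#'
#' @param m numeric probes x samples matrix with dimnames.
#' @param path output path (".gz" suffix compresses).
#' @export
write_beta_matrix <- function(m, path) {
  validate_betas(m)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with a \code{sample_id} column plus age / covariate columns.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE)
  if (!"sample_id" %in% names(df)) stopf("metadata %s lacks 'sample_id'", path)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_ids in %s", path)
  df
}

#' @rdname read_metadata
#' @param df metadata data.frame.
#' @export
write_metadata <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Intervals are 0-based half-open (the BED standard). Malformed lines are
#' reported with their line numbers. Output is sorted by (chromosome, start),
#' stably, regardless of input order.
#'
#' @param path BED file with >= 3 columns; column 4, if present, is kept as
#'   \code{name} (used for chromatin-state labels).
#' @param merge merge overlapping/adjacent intervals per chromosome
#'   (drops names).
#' @return data.frame with columns chrom, start, end and optionally name.
#' @export
read_bed <- function(path, merge = FALSE) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE, fill = TRUE)
  if (ncol(dt) < 3) stopf("BED %s: fewer than 3 columns", path)
  chrom <- as.character(dt[[1]])
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stopf("BED %s: malformed interval(s) at line(s) %s (need 0 <= start < end)",
          path, paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (merge) out <- merge_intervals(out)
  out
}

#' @rdname read_bed
#' @param intervals data.frame with chrom/start/end (and optional name,
#'   strand columns, written as BED columns 4 and 6).
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) {
    cols <- c(cols, list(intervals$name))
    if (!is.null(intervals$strand)) cols <- c(cols, list(0L, intervals$strand))
  }
  df <- as.data.frame(cols, col.names = paste0("V", seq_along(cols)))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Merge overlapping or book-ended intervals (half-open) per chromosome.
merge_intervals <- function(intervals) {
  gr <- intervals_to_granges(intervals)
  red <- GenomicRanges::reduce(gr)
  granges_to_intervals(red)
}

# Internal half-open 0-based <-> GRanges (1-based closed) conversion.
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# 450k-convention probe positions are 1-based; represent each probe as a
# width-1 range at its (1-based) position.
probes_to_granges <- function(probes) {
  GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(start = probes$pos, width = 1)
  )
}

#' Read / write a per-tissue aDMP result table
#'
#' @param path TSV as written by \code{write_admp_table}.
#' @return data.frame with the per-probe regression results and class calls.
#' @export
read_admp_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                    data.table = FALSE)
}

#' @rdname read_admp_table
#' @param calls an \code{admp_calls} object or its table.
#' @export
write_admp_table <- function(calls, path) {
  tab <- if (inherits(calls, "admp_calls")) calls$table else calls
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
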