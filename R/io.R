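# Plain-text readers/writers for the tabular formats used throughout:
# TSV manifests, count matrices, sample sheets, BED-like bin tables, CSV
# clinical tables. All coordinates in BED-like files are 0-based half-open.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read an element-by-sample count matrix
#'
#' Counts travel as TSV with an `element_id` first column and one column per
#' sample (header row = sample ids).
#'
#' @param counts integer matrix, rownames = element ids, colnames = sample ids.
#' @param path file path.
#' @return `read_counts` returns the integer matrix; `write_counts` the path,
#'   invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(element_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (!"element_id" %in% names(df))
    stop("counts file lacks an 'element_id' column: ", path, call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "element_id"), drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers: ", path, call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- df$element_id
  m
}

#' Write / read a sample sheet
#'
#' Columns: `sample_id`, `arm` (one of `T0`, `T14_untreated`, `T14_RT`),
#' `replicate`, `doublings` (cumulative population doublings since T0) and,
#' optionally, `fastq_path`.
#'
#' @param sheet data.frame sample sheet.
#' @param path file path.
#' @return `read_sample_sheet` returns the validated data.frame.
#' @export
write_sample_sheet <- function(sheet, path) write_tsv(sheet, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "arm", "replicate", "doublings")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$arm), c("T0", "T14_untreated", "T14_RT"))
  if (length(bad))
    stop("unknown arm(s) in sample sheet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  if (any(!is.finite(df$doublings)) || any(df$doublings < 0))
    stop("doublings must be non-negative", call. = FALSE)
  if (any(df$arm == "T0" & df$doublings != 0))
    stop("T0 samples must have doublings 0", call. = FALSE)
  df
}

#' Write / read bin-level copy-number profiles
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `log2ratio`
#' (0-based half-open coordinates).
#'
#' @param bins data.frame bin profile.
#' @param path file path.
#' @return `read_bins` returns the validated data.frame.
#' @export
write_bins <- function(bins, path) write_tsv(bins, path)

#' @rdname write_bins
#' @export
read_bins <- function(path) {
  df <- read_tsv(path)
  validate_bins(df)
}

validate_bins <- function(bins) {
  need <- c("chrom", "start", "end", "log2ratio")
  miss <- setdiff(need, names(bins))
  if (length(miss))
    stop("bin profile missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(bins$log2ratio)))
    stop("bin log2 ratios must be finite", call. = FALSE)
  if (any(bins$end <= bins$start))
    stop("bins must have end > start (0-based half-open)", call. = FALSE)
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE))
      stop("bins not sorted by start on ", ch, call. = FALSE)
    if (any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on ", ch, call. = FALSE)
  }
  bins
}

#' Read gene intervals from a BED file
#'
#' Expects at least four columns (chrom, start, end, name), 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
read_bed_genes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("gene BED needs 4 columns (chrom,start,end,name)",
                          call. = FALSE)
  g <- data.frame(name = df[[4L]], chrom = df[[1L]],
                  start = df[[2L]], end = df[[3L]],
                  stringsAsFactors = FALSE)
  if (anyDuplicated(g$name)) stop("duplicate gene names in BED", call. = FALSE)
  if (any(g$end <= g$start)) stop("gene intervals must have end > start",
                                  call. = FALSE)
  g
}

#' Write / read a clinical table
#'
#' CSV with per-patient `id`, `time` (local progression-free survival,
#' months), `event` (0/1 local progression), `purity` and `cd8_fraction`
#' in `[0, 1]`.
#'
#' @param clinical data.frame clinical table.
#' @param path file path.
#' @return `read_clinical` returns the validated data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("survival times must be positive", call. = FALSE)
  if (!all(df$event %in% c(0, 1, TRUE, FALSE)))
    stop("event must be 0/1", call. = FALSE)
  for (col in intersect(c("purity", "cd8_fraction"), names(df))) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1))
      stop(col, " must lie in [0, 1]", call. = FALSE)
  }
  df
}
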