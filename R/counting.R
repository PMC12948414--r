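# sgRNA barcode quantification from amplicon FASTQ.
#
# Matching is against the element barcode, anchored at the read start after
# an optional constant prefix. Tolerance-1 matching uses a precomputed
# Hamming-ball index; a read whose (trimmed) leading bases fall in the ball
# of two different barcodes is ambiguous and is never assigned.

# All sequences within Hamming distance 1 of each barcode (excluding itself).
hamming1_neighbors <- function(barcodes) {
  L <- nchar(barcodes[1L])
  bases <- c("A", "C", "G", "T")
  out <- vector("list", 4L * L)
  k <- 0L
  for (i in seq_len(L)) {
    cur <- substr(barcodes, i, i)
    pre <- substr(barcodes, 1L, i - 1L)
    post <- substr(barcodes, i + 1L, L)
    for (b in bases) {
      variant <- paste0(pre, b, post)
      variant[cur == b] <- NA_character_
      k <- k + 1L
      out[[k]] <- variant
    }
  }
  out
}

build_barcode_index <- function(barcodes, tolerance) {
  keys <- barcodes
  idx <- seq_along(barcodes)
  if (tolerance == 1L) {
    nb <- hamming1_neighbors(barcodes)
    keys <- c(keys, unlist(nb, use.names = FALSE))
    idx <- c(idx, rep(seq_along(barcodes), times = 4L * nchar(barcodes[1L])))
    keep <- !is.na(keys)
    keys <- keys[keep]; idx <- idx[keep]
    # a key claimed by two distinct elements marks barcodes within Hamming
    # distance <= 2 of each other: matching there would be ambiguous
    ord <- order(keys)
    keys <- keys[ord]; idx <- idx[ord]
    same_as_next <- c(keys[-1] == keys[-length(keys)], FALSE)
    ambig <- logical(length(keys))
    run_start <- which(same_as_next & !c(FALSE, same_as_next[-length(keys)]))
    if (length(run_start)) {
      in_run <- same_as_next | c(FALSE, same_as_next[-length(keys)])
      ambig[in_run] <- TRUE
      warning("barcode collision at tolerance 1 (barcodes within Hamming ",
              "distance 2); ambiguous reads will be unassigned", call. = FALSE)
    }
    idx[ambig] <- NA_integer_
    keep <- !duplicated(keys)
    keys <- keys[keep]; idx <- idx[keep]
  }
  list(keys = keys, idx = idx)
}

#' Count sgRNA barcodes in amplicon reads
#'
#' Tallies reads per library element and sample by exact or 1-mismatch
#' matching of the read's leading bases (after an optional constant prefix)
#' against the manifest barcodes. Reads matching no barcode, matching
#' ambiguously, or shorter than `prefix + barcode` are counted as unassigned,
#' so that `assigned + unassigned = total reads`, exactly.
#'
#' @param fastq named character vector of FASTQ paths (names = sample ids),
#'   or a sample sheet data.frame with `sample_id` and `fastq_path` columns.
#'   Gzip-compressed files are read transparently.
#' @param manifest a validated library manifest.
#' @param tolerance 0 (exact) or 1 (single substitution) mismatches.
#' @param prefix constant sequence expected before the barcode; its length
#'   is skipped (no sequence check).
#' @return a `barcode_counts` list: `counts` (integer matrix elements x
#'   samples), `unassigned` (named integer vector), `total` (named integer
#'   vector of input read counts), `tolerance`.
#' @export
count_barcodes <- function(fastq, manifest, tolerance = 0, prefix = "") {
  if (is.data.frame(fastq)) {
    if (!all(c("sample_id", "fastq_path") %in% names(fastq)))
      stop("sample sheet needs 'sample_id' and 'fastq_path' columns",
           call. = FALSE)
    paths <- stats::setNames(fastq$fastq_path, fastq$sample_id)
  } else {
    paths <- fastq
    if (is.null(names(paths)) || any(names(paths) == ""))
      stop("fastq paths must be named by sample id", call. = FALSE)
  }
  if (!tolerance %in% c(0L, 1L))
    stop("tolerance must be 0 or 1", call. = FALSE)
  check_manifest(manifest)
  L <- unique(nchar(manifest$barcode))
  if (length(L) != 1L)
    stop("barcode lengths must be uniform for counting", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)

  index <- build_barcode_index(manifest$barcode, as.integer(tolerance))
  off <- nchar(prefix)
  counts <- matrix(0L, nrow = nrow(manifest), ncol = length(paths),
                   dimnames = list(manifest$element_id, names(paths)))
  unassigned <- stats::setNames(integer(length(paths)), names(paths))
  total <- unassigned
  for (s in seq_along(paths)) {
    reads <- tryCatch(
      as.character(Biostrings::readDNAStringSet(paths[[s]], format = "fastq")),
      error = function(e) {
        if (length(readLines(paths[[s]], n = 1L)) == 0L) character(0)
        else stop(e)
      })
    total[s] <- length(reads)
    if (length(reads) == 0L) next
    long_enough <- nchar(reads) >= off + L
    key <- substr(reads[long_enough], off + 1L, off + L)
    hit <- index$idx[match(key, index$keys)]
    assigned <- hit[!is.na(hit)]
    if (length(assigned))
      counts[, s] <- counts[, s] +
        tabulate(assigned, nbins = nrow(manifest))
    unassigned[s] <- length(reads) - length(assigned)
  }
  structure(list(counts = counts, unassigned = unassigned, total = total,
                 tolerance = as.integer(tolerance)),
            class = "barcode_counts")
}
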