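#' Read and validate a dual-sgRNA library manifest
#'
#' The manifest is a TSV with columns `element_id`, `gene`, `protospacer_a`,
#' `protospacer_b`, `barcode`, `is_ntc`. One row is one barcoded dual-sgRNA
#' element; non-targeting control pairs carry `gene == "NTC"`. Row order is
#' preserved.
#'
#' @param path manifest TSV path.
#' @return a validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  df <- read_tsv(path)
  need <- c("element_id", "gene", "protospacer_a", "protospacer_b",
            "barcode", "is_ntc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$is_ntc <- as.logical(df$is_ntc)
  check_manifest(df)
  df
}

check_manifest <- function(df) {
  if (nrow(df) == 0L) stop("manifest is empty", call. = FALSE)
  dup_id <- unique(df$element_id[duplicated(df$element_id)])
  if (length(dup_id))
    stop("duplicate element_id(s): ", paste(dup_id, collapse = ", "),
         call. = FALSE)
  dup_bc <- unique(df$barcode[duplicated(df$barcode)])
  if (length(dup_bc))
    stop("duplicate barcode(s): ", paste(dup_bc, collapse = ", "),
         call. = FALSE)
  for (col in c("protospacer_a", "protospacer_b", "barcode")) {
    bad <- grepl("[^ACGT]", df[[col]])
    if (any(bad))
      stop("non-ACGT characters in ", col, " for element(s): ",
           paste(utils::head(df$element_id[bad], 5L), collapse = ", "),
           call. = FALSE)
  }
  plen <- c(nchar(df$protospacer_a), nchar(df$protospacer_b))
  if (any(plen < 19L | plen > 21L))
    stop("protospacers must be 19-21 nt", call. = FALSE)
  mism <- xor(df$is_ntc, df$gene == "NTC")
  if (any(mism))
    stop("is_ntc flag inconsistent with gene == 'NTC' for element(s): ",
         paste(utils::head(df$element_id[mism], 5L), collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Write a library manifest as TSV
#'
#' @param manifest manifest data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  check_manifest(manifest)
  write_tsv(manifest, path)
}

#' Summarize a library manifest
#'
#' Report-only companion to [read_manifest()]: composition counts and length
#' distributions, plus duplicate checks (always clean for a manifest that
#' passed loading).
#'
#' @param manifest a validated manifest data.frame.
#' @return a list: `n_elements`, `gene_count` (gene-targeting elements),
#'   `ntc_count`, `n_unique_genes`, `duplicate_element_ids`,
#'   `duplicate_barcodes`, `barcode_lengths` (table),
#'   `protospacer_length_range`.
#' @export
validate_manifest <- function(manifest) {
  check_manifest(manifest)
  list(n_elements = nrow(manifest),
       gene_count = sum(!manifest$is_ntc),
       ntc_count = sum(manifest$is_ntc),
       n_unique_genes = length(unique(manifest$gene[!manifest$is_ntc])),
       duplicate_element_ids = character(0),
       duplicate_barcodes = character(0),
       barcode_lengths = table(nchar(manifest$barcode)),
       protospacer_length_range =
         range(c(nchar(manifest$protospacer_a),
                 nchar(manifest$protospacer_b))))
}
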