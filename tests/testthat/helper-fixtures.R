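# Small in-code fixtures shared across test files.

tiny_manifest <- function() {
  data.frame(
    element_id = c("GENE1_ds", "GENE2_ds", "NTC1"),
    gene = c("GENE1", "GENE2", "NTC"),
    protospacer_a = c("ACGTACGTACGTACGTACGT", "TTGCATGCATGCATGCATGC",
                      "GGGTACGTTACGATCGATCG"),
    protospacer_b = c("CCGTACGTACGTACGTACGT", "ATGCATGCATGCATGCATGA",
                      "TGGTACGTTACGATCGATCA"),
    barcode = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
                "GGATCCGGATCCGGATCCGG"),
    is_ntc = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

write_fastq <- function(seqs, path, qual_char = "I") {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  rec <- paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n",
                strrep(qual_char, nchar(seqs)))
  writeLines(rec, path)
  invisible(path)
}

# Minimal sample sheet for hand-built count matrices: one T0, one untreated
# and one RT arm with `n` replicates each, untreated doublings `du`, RT `dr`.
tiny_sheet <- function(n = 2, du = 10, dr = 7) {
  data.frame(
    sample_id = c(paste0("T0_", 1:n), paste0("untreated_", 1:n),
                  paste0("RT_", 1:n)),
    arm = rep(c("T0", "T14_untreated", "T14_RT"), each = n),
    replicate = rep(1:n, 3),
    doublings = rep(c(0, du, dr), each = n),
    stringsAsFactors = FALSE)
}

# Count matrix from per-arm per-element values (elements x n per arm).
tiny_counts <- function(t0, untreated, rt, sheet) {
  m <- cbind(t0, untreated, rt)
  colnames(m) <- sheet$sample_id
  rownames(m) <- paste0("el", seq_len(nrow(m)))
  storage.mode(m) <- "integer"
  m
}
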