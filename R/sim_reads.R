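#' Emit FASTQ reads for a simulated screen
#'
#' Writes one FASTQ file per sample, with one read per sampled count. Each
#' read is the element's barcode with iid substitution errors at
#' `error_rate`; qualities are constant Phred+33 'I'. Counting the output
#' with [count_barcodes()] at a matching tolerance recovers the simulated
#' count matrix.
#'
#' @param sim a `screen_sim` from [simulate_screen()].
#' @param error_rate per-base substitution probability, in `[0, 0.1]`.
#' @param seed integer seed for error placement and read shuffling.
#' @param dir output directory for the FASTQ files.
#' @param prefix optional constant sequence prepended to every read
#'   (amplicon handle upstream of the barcode).
#' @return the sample sheet with a `fastq_path` column added, invisibly.
#' @export
simulate_reads <- function(sim, error_rate = 0, seed = 1, dir,
                           prefix = "") {
  stopifnot(inherits(sim, "screen_sim"))
  assert_number(error_rate, "error_rate", lower = 0, upper = 0.1)
  assert_number(seed, "seed", integer = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bases <- c("A", "C", "G", "T")
  L <- nchar(sim$manifest$barcode[1L])
  sheet <- sim$sample_sheet
  sheet$fastq_path <- file.path(dir, paste0(sheet$sample_id, ".fastq"))
  qual <- strrep("I", nchar(prefix) + L)
  for (s in seq_len(nrow(sheet))) {
    cts <- sim$counts[, sheet$sample_id[s]]
    seqs <- rep(sim$manifest$barcode, cts)
    n_reads <- length(seqs)
    if (n_reads > 0L) {
      with_seed(derive_seed(seed, 100L + s), {
        seqs <- sample(seqs)
        if (error_rate > 0) {
          chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                          nrow = n_reads, byrow = TRUE)
          hit <- which(matrix(stats::runif(n_reads * L) < error_rate,
                              nrow = n_reads))
          if (length(hit)) {
            # substitute with a uniformly chosen *different* base
            shift <- sample(3L, length(hit), replace = TRUE)
            cur <- match(chars[hit], bases)
            chars[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
            seqs <- apply(chars, 1L, paste0, collapse = "")
          }
        }
      })
    }
    con <- file(sheet$fastq_path[s], "w")
    if (n_reads > 0L) {
      rec <- paste0("@", sheet$sample_id[s], "_read", seq_len(n_reads), "\n",
                    prefix, seqs, "\n+\n", qual)
      writeLines(rec, con)
    }
    close(con)
  }
  invisible(sheet)
}
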