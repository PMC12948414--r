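# Gene-set overrepresentation by one-sided Fisher's exact test, run
# generically against user-supplied gene collections (GMT format).

#' Gene-set overrepresentation test
#'
#' For each gene set, forms the 2x2 table of hit membership vs set membership
#' within the universe and computes the one-sided (enrichment)
#' Fisher's exact p — the hypergeometric upper tail of the observed overlap —
#' plus the sample odds ratio, with BH adjustment across sets.
#'
#' @param hits character vector of hit genes; must be a subset of `universe`.
#' @param gene_sets named list of character vectors; each set is intersected
#'   with the universe before testing.
#' @param universe character vector of all scored genes.
#' @return data.frame with one row per set: `set`, `set_size` (within
#'   universe), `n_hits`, `overlap`, `odds_ratio`, `p_value`, `p_adj`.
#' @examples
#' overrepresentation_test(
#'   hits = paste0("g", 1:5),
#'   gene_sets = list(myset = paste0("g", c(1:4, 10))),
#'   universe = paste0("g", 1:20))
#' @export
overrepresentation_test <- function(hits, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  hits <- unique(hits)
  out_of_universe <- setdiff(hits, universe)
  if (length(out_of_universe))
    stop("hit gene(s) not in universe: ",
         paste(utils::head(out_of_universe, 5L), collapse = ", "),
         call. = FALSE)
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("gene_sets must be a named list", call. = FALSE)
  N <- length(universe)
  n <- length(hits)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(hits, set))
    # P(X >= k), X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; c_ <- K - k; d <- (N - K) - b
    or <- (a * d) / (b * c_)  # sample odds ratio; Inf/NaN on empty margins
    data.frame(set = nm, set_size = K, n_hits = n, overlap = k,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- adjust_bh(res$p_value)
  res[order(res$p_value), , drop = FALSE]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[[`, "", 1L))
}

#' Write gene sets in GMT format
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return the path, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
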