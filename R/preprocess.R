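#' Counts-per-million normalisation
#'
#' Scales each sample column to a library size of one million reads:
#' `value[g, s] = counts[g, s] / colsum(s) * 1e6`. This is the normalisation
#' used upstream of the coordination analysis; correlation is computed on raw
#' CPM by default, with `log2(CPM + pseudocount)` available as an explicit
#' opt-in.
#'
#' @param counts Counts tibble (`gene_id` + sample columns).
#' @param log_transform If `TRUE`, return `log2(CPM + pseudocount)`.
#' @param pseudocount Added before the log (default 1).
#' @param min_mean_cpm Drop genes whose mean CPM across samples is below this
#'   value (default 0 = keep all genes; no expression filter is applied
#'   unless requested).
#' @return An expression tibble with attribute `transform` set to `"cpm"` or
#'   `"log2cpm"`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("A", "B"), s1 = c(10, 90))
#' cpm_normalize(counts)
cpm_normalize <- function(counts, log_transform = FALSE, pseudocount = 1,
                          min_mean_cpm = 0) {
  counts <- validate_counts(counts)
  m <- expr_matrix(counts)
  libs <- colSums(m)
  zero <- names(libs)[libs == 0]
  if (length(zero) > 0) {
    cpc_abort(paste0("zero library size in sample(s): ",
                     paste(zero, collapse = ", ")))
  }
  cpm <- sweep(m, 2, libs, "/") * 1e6
  if (min_mean_cpm > 0) {
    keep <- rowMeans(cpm) >= min_mean_cpm
    cpm <- cpm[keep, , drop = FALSE]
    if (nrow(cpm) == 0) cpc_abort("min_mean_cpm filter removed every gene")
  }
  tag <- "cpm"
  if (log_transform) {
    cpm <- log2(cpm + pseudocount)
    tag <- "log2cpm"
  }
  out <- expr_tbl(cpm)
  attr(out, "transform") <- tag
  out
}

#' Restrict two expression tables to their common gene universe
#'
#' Pc requires the same gene universe in both conditions of a cohort. When the
#' two conditions were quantified separately their gene sets can differ; this
#' keeps the intersection, in the gene order of `a`, and reports how many
#' genes were dropped from each side. An empty intersection is an error.
#'
#' @param a,b Expression (or counts) tibbles.
#' @param quiet Suppress the dropped-genes message.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   genes in identical order, plus `dropped_a` / `dropped_b` ID vectors.
#' @export
harmonize_genes <- function(a, b, quiet = FALSE) {
  a <- validate_counts(a, "expression")
  b <- validate_counts(b, "expression")
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) == 0) cpc_abort("no genes shared between the two tables")
  dropped_a <- setdiff(a$gene_id, shared)
  dropped_b <- setdiff(b$gene_id, shared)
  if (!quiet && (length(dropped_a) > 0 || length(dropped_b) > 0)) {
    message(sprintf("harmonize_genes: kept %d shared genes (dropped %d from a, %d from b)",
                    length(shared), length(dropped_a), length(dropped_b)))
  }
  ord <- a$gene_id[a$gene_id %in% shared]   # canonical order = order in `a`
  list(
    a = a[match(ord, a$gene_id), , drop = FALSE],
    b = b[match(ord, b$gene_id), , drop = FALSE],
    dropped_a = dropped_a,
    dropped_b = dropped_b
  )
}
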