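# Accepts a pc_fit or a per-gene tibble with pc / status columns.
pc_values <- function(pc) {
  tbl <- if (inherits(pc, "pc_fit")) pc$table else tibble::as_tibble(pc)
  if (!all(c("gene_id", "pc") %in% names(tbl))) {
    cpc_abort("need a pc_fit or a table with gene_id and pc columns")
  }
  if (!"status" %in% names(tbl)) tbl$status <- ifelse(is.na(tbl$pc), "undefined", "ok")
  dplyr::filter(tbl, .data$status == "ok", !is.na(.data$pc))
}

#' Summarise a Pc table
#'
#' Mean and median Pc, the percentage of genes with negative Pc (coordination
#' inversion), and the number of analysed genes. Statistics cover genes with
#' `status == "ok"` only; flagged genes never contribute an imputed value.
#' Both mean and median are always reported because cohort-level differences
#' are typically quoted as averages while distribution plots show medians.
#'
#' @param pc A `pc_fit` or a per-gene Pc tibble.
#' @return A one-row tibble: `mean_pc`, `median_pc`,
#'   `fraction_negative_percent` (0-100), `g_analyzed`.
#' @export
summarize_pc <- function(pc) {
  ok <- pc_values(pc)
  if (nrow(ok) == 0) cpc_abort("no analysable genes (status ok) in Pc table")
  tibble::tibble(
    mean_pc = mean(ok$pc),
    median_pc = median(ok$pc),
    fraction_negative_percent = 100 * mean(ok$pc < 0),
    g_analyzed = nrow(ok)
  )
}

mann_whitney <- function(x, y) {
  ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  tibble::tibble(test = "mann_whitney_u",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value)
}

welch <- function(x, y) {
  ht <- t.test(x, y)
  tibble::tibble(test = "welch_t",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value)
}

#' Compare Pc distributions between two cohorts
#'
#' Two transcriptomes rarely have the same number of analysed genes, and a
#' raw rank test across unequal gene universes conflates distributional and
#' size differences. Two comparisons are therefore reported: (a) the raw
#' two-sided Mann-Whitney U test on all analysed Pc values, and (b) a
#' size-normalised comparison in which the larger cohort's Pc values are
#' repeatedly subsampled without replacement down to the smaller cohort's
#' size, the test recomputed each draw, and the median statistic and p-value
#' reported together with their across-draw spread. When the cohorts are
#' already equal-sized the subsampling is a no-op and every draw equals the
#' raw test. A quartile (top/bottom 25%) tail report is included.
#'
#' @param pc_a,pc_b `pc_fit` objects or Pc tibbles for the two cohorts.
#' @param labels Character vector of length 2 naming the cohorts.
#' @param n_draws Number of subsampling draws (default 100).
#' @param seed Seed for the subsampling draws.
#' @param test `"mann_whitney"` (default; Pc distributions are bounded and
#'   non-normal) or `"welch"`.
#' @return A `pc_comparison` object; [tidy()] returns the per-cohort summary
#'   table, [glance()] a one-row overview.
#' @export
compare_cohorts <- function(pc_a, pc_b, labels = c("a", "b"),
                            n_draws = 100, seed = NULL,
                            test = c("mann_whitney", "welch")) {
  test <- match.arg(test)
  if (n_draws < 1) cpc_abort("n_draws must be >= 1")
  a <- pc_values(pc_a)
  b <- pc_values(pc_b)
  if (nrow(a) < 4 || nrow(b) < 4) cpc_abort("each cohort needs >= 4 analysable genes")
  tfun <- if (test == "mann_whitney") mann_whitney else welch

  raw <- tfun(a$pc, b$pc)
  g_small <- min(nrow(a), nrow(b))

  draw_one <- function(...) {
    xa <- if (nrow(a) > g_small) sample(a$pc, g_small) else a$pc
    xb <- if (nrow(b) > g_small) sample(b$pc, g_small) else b$pc
    tfun(xa, xb)
  }
  draws <- with_local_seed(seed, purrr::map_dfr(seq_len(n_draws), draw_one))
  normalized <- tibble::tibble(
    test = raw$test,
    statistic = median(draws$statistic),
    p_value = median(draws$p_value),
    p_value_q25 = quantile(draws$p_value, 0.25, names = FALSE),
    p_value_q75 = quantile(draws$p_value, 0.75, names = FALSE),
    n_draws = n_draws,
    subsample_size = g_small
  )

  summaries <- dplyr::bind_rows(summarize_pc(a), summarize_pc(b)) |>
    tibble::add_column(cohort = labels, .before = 1)

  structure(
    list(
      cohorts = summaries,
      raw = raw,
      normalized = normalized,
      quartiles = quartile_report(pc_a, pc_b, labels = labels, test = test),
      meta = list(labels = labels, test = test, n_draws = n_draws,
                  seed = seed, subsample_size = g_small,
                  normalization = "equal_size_subsample")
    ),
    class = "pc_comparison"
  )
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Quartile (distribution-tail) report for two cohorts
#'
#' Extracts the bottom and top 25% of analysed genes by Pc in each cohort and
#' compares the tails across cohorts with a two-sided test. A cohort whose
#' coordination changes are fewer but more drastic shows a lower
#' bottom-quartile median and a higher top-quartile median -- a wider Pc range
#' -- than a cohort undergoing broad but subtle reorganisation.
#'
#' @inheritParams compare_cohorts
#' @return A tibble with one row per tail (`bottom`, `top`): per-cohort
#'   medians, quartile sizes, and the cross-cohort p-value.
#' @export
quartile_report <- function(pc_a, pc_b, labels = c("a", "b"),
                            test = c("mann_whitney", "welch")) {
  test <- match.arg(test)
  a <- pc_values(pc_a)
  b <- pc_values(pc_b)
  if (nrow(a) < 8 || nrow(b) < 8) {
    cpc_abort("quartile report needs >= 8 analysable genes per cohort")
  }
  tfun <- if (test == "mann_whitney") mann_whitney else welch
  tail_of <- function(tbl, dir) {
    k <- floor(nrow(tbl) / 4)
    top_ranked(tbl, k = k, direction = dir)$pc
  }
  purrr::map_dfr(c(bottom = "lowest", top = "highest"), function(dir) {
    ta <- tail_of(a, dir)
    tb <- tail_of(b, dir)
    ht <- tfun(ta, tb)
    tibble::tibble(
      median_a = median(ta), median_b = median(tb),
      n_a = length(ta), n_b = length(tb),
      statistic = ht$statistic, p_value = ht$p_value
    )
  }, .id = "tail") |>
    dplyr::rename_with(~ sub("_a$", paste0("_", labels[1]), sub("_b$", paste0("_", labels[2]), .x)),
                       dplyr::matches("_[ab]$"))
}

#' @export
print.pc_comparison <- function(x, ...) {
  cat("<pc_comparison>", paste(x$meta$labels, collapse = " vs "), "\n")
  print(x$cohorts)
  cat(sprintf("raw %s: W = %.4g, p = %.3g\n",
              x$raw$test, x$raw$statistic, x$raw$p_value))
  cat(sprintf("size-normalised (n = %d draws to G = %d): median p = %.3g [IQR %.3g, %.3g]\n",
              x$normalized$n_draws, x$normalized$subsample_size,
              x$normalized$p_value, x$normalized$p_value_q25, x$normalized$p_value_q75))
  invisible(x)
}

#' @rdname compare_cohorts
#' @param x A `pc_comparison` object.
#' @param ... Unused.
#' @method tidy pc_comparison
#' @export
tidy.pc_comparison <- function(x, ...) x$cohorts

#' @rdname compare_cohorts
#' @method glance pc_comparison
#' @export
glance.pc_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$raw$test,
    statistic = x$raw$statistic,
    p_value = x$raw$p_value,
    normalized_p_value = x$normalized$p_value,
    subsample_size = x$normalized$subsample_size,
    n_draws = x$normalized$n_draws
  )
}

#' Top-ranked genes by Pc
#'
#' The `k` genes with the highest (coordination most stringently retained) or
#' lowest (most strongly inverted) Pc, over analysable genes only. Ties are
#' broken lexicographically by gene ID so rankings are deterministic; `k`
#' beyond the number of analysable genes returns the full sorted list.
#'
#' @param pc A `pc_fit` or Pc tibble.
#' @param k Number of genes to return (default 10).
#' @param direction `"highest"` or `"lowest"`.
#' @return A tibble `gene_id`, `pc`, `rank`, sorted in ranking order.
#' @export
top_ranked <- function(pc, k = 10, direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  if (k < 1) cpc_abort("k must be >= 1")
  ok <- pc_values(pc)
  ord <- if (direction == "highest") {
    order(-ok$pc, ok$gene_id)
  } else {
    order(ok$pc, ok$gene_id)
  }
  out <- ok[head(ord, k), c("gene_id", "pc")]
  out$rank <- seq_len(nrow(out))
  out
}

#' Export lowest-Pc genes for external enrichment tools
#'
#' Writes the `k` genes with the lowest Pc (strongest coordination inversion)
#' as a plain one-gene-per-line list, ready to paste into GO/pathway
#' enrichment web tools. The enrichment itself is outside this package's
#' scope (it depends on external annotation databases).
#'
#' @param pc A `pc_fit` or Pc tibble.
#' @param path Output file path.
#' @param k Number of genes (default 500); clamped to the analysable count.
#' @return The character vector of gene IDs written, invisibly.
#' @export
export_go_candidates <- function(pc, path, k = 500) {
  ids <- top_ranked(pc, k = k, direction = "lowest")$gene_id
  writeLines(ids, path)
  invisible(ids)
}

#' Differential expression of one gene between conditions
#'
#' Fold change of mean expression (old over young) with a two-sided Welch
#' t-test, used to check whether a coordination change is accompanied by a
#' plain expression change -- genes can invert their coordination profile
#' while their expression level barely moves.
#'
#' @param young,old Expression tibbles (typically CPM) containing `gene`.
#' @param gene A single gene ID.
#' @param geometric Use the geometric mean for the fold change (default
#'   arithmetic, matching how relative-expression bar plots are drawn).
#' @return One-row tibble: `gene_id`, `mean_young`, `mean_old`, `fold_change`,
#'   `p_value`, `status` (`"ok"`, or `"undefined_fold"` when the young mean
#'   is 0).
#' @export
relative_expression_test <- function(young, old, gene, geometric = FALSE) {
  stopifnot(length(gene) == 1)
  young <- validate_counts(young, "expression")
  old <- validate_counts(old, "expression")
  if (!gene %in% young$gene_id || !gene %in% old$gene_id) {
    cpc_abort(paste0("gene not present in both matrices: ", gene))
  }
  xy <- as.numeric(young[match(gene, young$gene_id), -1])
  xo <- as.numeric(old[match(gene, old$gene_id), -1])
  avg <- if (geometric) function(v) exp(mean(log(v))) else mean
  my <- avg(xy)
  mo <- avg(xo)
  fc <- if (my == 0) NA_real_ else mo / my
  p <- if (sd(xy) == 0 && sd(xo) == 0) {
    if (isTRUE(all.equal(my, mo))) 1 else NA_real_
  } else {
    t.test(xo, xy)$p.value
  }
  tibble::tibble(
    gene_id = gene, mean_young = my, mean_old = mo,
    fold_change = fc, p_value = p,
    status = if (is.na(fc)) "undefined_fold" else "ok"
  )
}
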