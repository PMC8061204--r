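#' Pearson correlation with explicit zero-variance handling
#'
#' Standard product-moment correlation of two equal-length vectors. Returns
#' `NA` (flagged undefined) when either vector is constant, rather than
#' propagating a divide-by-zero; errors on length mismatch or fewer than
#' 3 points, where the estimate is meaningless.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single number in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
#' @examples
#' pearson_r(1:3, c(2, 4, 6))   # 1
#' pearson_r(1:3, c(3, 2, 1))   # -1
#' pearson_r(1:3, c(5, 5, 5))   # NA: zero variance
pearson_r <- function(x, y) {
  if (length(x) != length(y)) cpc_abort("x and y must have equal length")
  if (length(x) < 3) cpc_abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  clip_r(cor(x, y))
}

# Numerical guard: crossproduct correlations can exceed |1| by rounding error.
clip_r <- function(r, tol = 1e-12) {
  r[!is.na(r) & r > 1 & r <= 1 + tol] <- 1
  r[!is.na(r) & r < -1 & r >= -1 - tol] <- -1
  pmin(pmax(r, -1), 1)
}

# Internal: rows standardized so that tcrossprod gives Pearson correlations.
# Zero-variance rows come back as all-NA and are the caller's business.
scale_rows <- function(m) {
  mu <- rowMeans(m)
  cen <- m - mu
  ss <- sqrt(rowSums(cen^2))
  z <- cen / ss
  z[ss == 0, ] <- NA_real_
  z
}

# Internal: drop genes that are constant in either matrix; returns the status
# vector for all input genes and the row-standardized matrices of the survivors.
prepare_universe <- function(my, mo) {
  vy <- apply(my, 1, sd) > 0
  vo <- apply(mo, 1, sd) > 0
  status <- rep("ok", nrow(my))
  status[!vy] <- "zero_variance_young"
  status[vy & !vo] <- "zero_variance_old"
  ok <- vy & vo
  list(
    status = status,
    ok = ok,
    zy = scale_rows(my[ok, , drop = FALSE]),
    zo = scale_rows(mo[ok, , drop = FALSE])
  )
}

#' Per-gene correlation profiles within one condition
#'
#' For each requested gene, the Pearson correlation of its expression with
#' every other analysed gene in the matrix (the gene's "coordination profile").
#' The gene's self-correlation (identically 1) is excluded. Genes with zero
#' variance across samples cannot be correlated and are excluded from the
#' analysed set -- both as focal genes and as partners -- and reported via the
#' `excluded` attribute.
#'
#' Profiles are computed in blocks of `block_size` focal genes at a time, so
#' peak memory is proportional to `G * block_size` rather than `G^2`.
#'
#' @param expr Expression tibble (`gene_id` + >= 3 sample columns, >= 4 genes).
#' @param genes Focal genes to profile (default: all analysed genes).
#' @param block_size Number of focal genes per block (default 1024). The
#'   result is exactly independent of this value.
#' @return A long tibble with columns `gene_id`, `partner_id`, `r`, in
#'   canonical (input) gene order; attribute `excluded` lists zero-variance
#'   genes.
#' @export
correlation_profiles <- function(expr, genes = NULL, block_size = 1024) {
  expr <- validate_counts(expr, "expression", allow_negative = TRUE)
  m <- expr_matrix(expr)
  if (ncol(m) < 3) cpc_abort("need at least 3 samples per condition")
  if (nrow(m) < 4) cpc_abort("need at least 4 genes")
  keep <- apply(m, 1, sd) > 0
  if (!any(keep)) cpc_abort("all genes have zero variance")
  excluded <- rownames(m)[!keep]
  z <- scale_rows(m[keep, , drop = FALSE])
  ids <- rownames(z)
  genes <- genes %||% ids
  bad <- setdiff(genes, ids)
  if (length(bad) > 0) {
    cpc_abort(paste0("gene(s) not in the analysed universe: ",
                     paste(head(bad, 5), collapse = ", ")))
  }
  idx <- match(genes, ids)
  out <- vector("list", length(blocks <- split(idx, ceiling(seq_along(idx) / block_size))))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    r <- clip_r(tcrossprod(z[b, , drop = FALSE], z))
    out[[bi]] <- purrr::map2_dfr(seq_along(b), b, function(i, gi) {
      tibble::tibble(gene_id = ids[gi], partner_id = ids[-gi], r = unname(r[i, -gi]))
    })
  }
  res <- dplyr::bind_rows(out)
  attr(res, "excluded") <- excluded
  res
}

#' Composite correlation index (Pc) between two conditions
#'
#' The central statistic: for each gene, the Pearson correlation between its
#' vector of gene-gene correlations in the first condition (young) and the
#' matching vector in the second (old), taken over all other analysed genes.
#' Pc near 1 indicates the gene's co-expression profile is retained across
#' conditions; negative Pc indicates it inverted.
#'
#' Genes constant in either condition are flagged
#' (`zero_variance_young` / `zero_variance_old`), excluded both as focal genes
#' and as partners, and carry an undefined Pc -- never an imputed number.
#' Partners whose correlation is undefined in one condition are dropped
#' pairwise from both vectors, with `n_partners_used` recording the remainder;
#' fewer than 3 usable partners flags the gene `insufficient_partners`.
#' The self-correlation (1 in both conditions) is excluded from the profile:
#' including it would mechanically inflate every Pc toward +1.
#'
#' The full gene-gene correlation matrices are never materialised; focal genes
#' are processed in blocks of `block_size`, so memory stays proportional to
#' `G * block_size`. The result is exactly independent of `block_size`.
#'
#' @param young,old Expression tibbles on the same gene universe (see
#'   [harmonize_genes()]), each with >= 3 samples.
#' @param block_size Focal-gene block size (default 1024).
#' @return A `pc_fit` object. [tidy()] returns the per-gene table
#'   (`gene_id`, `pc`, `n_partners_used`, `status`); [glance()] the cohort
#'   summary; [autoplot()] the Pc distribution.
#' @export
#' @examples
#' sim <- simulate_coordination(sim_params(G = 40, S = 6, M = 4, seed = 1))
#' fit <- composite_pc(cpm_normalize(sim$counts_young),
#'                     cpm_normalize(sim$counts_old))
#' glance(fit)
composite_pc <- function(young, old, block_size = 1024) {
  young <- validate_counts(young, "expression", allow_negative = TRUE)
  old <- validate_counts(old, "expression", allow_negative = TRUE)
  if (!identical(young$gene_id, old$gene_id)) {
    cpc_abort("young and old must share an identical, ordered gene universe; run harmonize_genes() first")
  }
  my <- expr_matrix(young)
  mo <- expr_matrix(old)
  if (ncol(my) < 3 || ncol(mo) < 3) cpc_abort("need at least 3 samples per condition")
  if (nrow(my) < 4) cpc_abort("need at least 4 genes")

  u <- prepare_universe(my, mo)
  ids_all <- young$gene_id
  ids_ok <- ids_all[u$ok]
  g_ok <- length(ids_ok)
  if (g_ok < 4) cpc_abort("fewer than 4 genes with non-zero variance in both conditions")

  pc <- rep(NA_real_, g_ok)
  npart <- rep(NA_integer_, g_ok)
  blocks <- split(seq_len(g_ok), ceiling(seq_len(g_ok) / block_size))
  for (b in blocks) {
    ry <- clip_r(tcrossprod(u$zy[b, , drop = FALSE], u$zy))
    ro <- clip_r(tcrossprod(u$zo[b, , drop = FALSE], u$zo))
    # mask the focal gene's own column in each row
    ry[cbind(seq_along(b), b)] <- NA_real_
    ro[cbind(seq_along(b), b)] <- NA_real_
    use <- !is.na(ry) & !is.na(ro)
    ry[!use] <- NA_real_
    ro[!use] <- NA_real_
    n <- rowSums(use)
    res <- row_pearson(ry, ro, n)
    npart[b] <- as.integer(n)
    pc[b] <- res
  }
  status <- u$status
  pc_all <- rep(NA_real_, length(ids_all))
  np_all <- rep(NA_integer_, length(ids_all))
  pc_all[u$ok] <- pc
  np_all[u$ok] <- npart
  low <- u$ok & !is.na(np_all) & np_all < 3
  status[low] <- "insufficient_partners"
  pc_all[low] <- NA_real_

  tbl <- tibble::tibble(
    gene_id = ids_all,
    pc = pc_all,
    n_partners_used = np_all,
    status = status
  )
  structure(
    list(
      table = tbl,
      meta = list(
        g_input = length(ids_all),
        g_analyzed = sum(tbl$status == "ok"),
        s_young = ncol(my),
        s_old = ncol(mo),
        block_size = block_size
      )
    ),
    class = "pc_fit"
  )
}

# Vectorized per-row Pearson between two matrices with aligned NA patterns.
# n gives the per-row count of usable (non-NA) pairs.
row_pearson <- function(a, b, n) {
  ma <- rowSums(a, na.rm = TRUE) / n
  mb <- rowSums(b, na.rm = TRUE) / n
  ac <- a - ma
  bc <- b - mb
  ac[is.na(a)] <- 0
  bc[is.na(b)] <- 0
  num <- rowSums(ac * bc)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  out <- rep(NA_real_, nrow(a))
  good <- den > 0 & n >= 3
  out[good] <- num[good] / den[good]
  clip_r(out)
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf(
    "<pc_fit> %d genes analysed (of %d input), %d + %d samples\n",
    x$meta$g_analyzed, x$meta$g_input, x$meta$s_young, x$meta$s_old
  ))
  print(glance(x))
  invisible(x)
}

#' @rdname composite_pc
#' @param x A `pc_fit` object.
#' @param ... Unused.
#' @method tidy pc_fit
#' @export
tidy.pc_fit <- function(x, ...) x$table

#' @rdname composite_pc
#' @method glance pc_fit
#' @export
glance.pc_fit <- function(x, ...) summarize_pc(x)

#' Paired correlation profiles of one gene in two conditions
#'
#' Returns, for a single gene, its aligned correlation vectors against all
#' shared analysed partners in the young and old condition -- the raw material
#' for the per-gene violin plots that show a coordination inversion (partners
#' positively correlated in youth turning negative with age, and vice versa).
#'
#' @param young,old Expression tibbles on the same gene universe.
#' @param gene A single gene ID, analysable (non-constant) in both conditions.
#' @return A tibble with columns `partner_id`, `r_young`, `r_old`, one row per
#'   partner defined in both conditions.
#' @export
gene_r_profiles <- function(young, old, gene) {
  stopifnot(length(gene) == 1)
  young <- validate_counts(young, "expression", allow_negative = TRUE)
  old <- validate_counts(old, "expression", allow_negative = TRUE)
  if (!identical(young$gene_id, old$gene_id)) {
    cpc_abort("young and old must share an identical, ordered gene universe")
  }
  if (!gene %in% young$gene_id) {
    cpc_abort(paste0("unknown gene: ", gene))
  }
  u <- prepare_universe(expr_matrix(young), expr_matrix(old))
  ids_ok <- young$gene_id[u$ok]
  if (!gene %in% ids_ok) {
    cpc_abort(paste0("gene has zero variance in at least one condition: ", gene))
  }
  i <- match(gene, ids_ok)
  ry <- clip_r(drop(tcrossprod(u$zy[i, , drop = FALSE], u$zy)))[-i]
  ro <- clip_r(drop(tcrossprod(u$zo[i, , drop = FALSE], u$zo)))[-i]
  keep <- !is.na(ry) & !is.na(ro)
  tibble::tibble(
    partner_id = ids_ok[-i][keep],
    r_young = unname(ry[keep]),
    r_old = unname(ro[keep])
  )
}
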