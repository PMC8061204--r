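#' Read a gene-by-sample counts matrix
#'
#' Counts tables are tibbles with a `gene_id` character column followed by one
#' numeric column per sample. Two on-disk layouts are supported: tab-separated
#' text with gene IDs in the first column and sample IDs in the header row,
#' and MatrixMarket sparse format (`.mtx`) with plain-text sidecar files
#' listing gene and sample IDs (one per line).
#'
#' Duplicated gene or sample IDs are rejected rather than silently merged,
#' and negative or non-numeric counts are an error. A table that looks
#' transposed (samples in rows) cannot be detected reliably, so the layout is
#' fixed by contract: genes in rows, always.
#'
#' @param path Path to the counts file (`.tsv`/`.txt` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`; `"auto"` (default) picks by extension.
#' @param genes,samples For `mtx` input, paths to the gene- and sample-ID
#'   sidecar files. Default: `<stem>.genes.txt` and `<stem>.samples.txt`
#'   next to the matrix.
#' @return A counts tibble: `gene_id` plus one integer-valued column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "GeneA\t10\t0", "GeneB\t5\t5"), tf)
#' read_counts(tf)
read_counts <- function(path, format = c("auto", "tsv", "mtx"),
                        genes = NULL, samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    cpc_abort(paste0("counts file not found: ", path), "coordpc_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    tbl <- readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE, name_repair = "minimal")
    if (ncol(tbl) < 2) {
      cpc_abort("counts TSV needs a gene ID column plus >= 1 sample column",
                "coordpc_format_error")
    }
    names(tbl)[1] <- "gene_id"
    for (j in seq(2, ncol(tbl))) {
      v <- suppressWarnings(as.numeric(tbl[[j]]))
      if (anyNA(v)) {
        cpc_abort(paste0("non-numeric or missing counts in column ",
                         names(tbl)[j]), "coordpc_validation_error")
      }
      tbl[[j]] <- v
    }
  } else {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    genes <- genes %||% paste0(stem, ".genes.txt")
    samples <- samples %||% paste0(stem, ".samples.txt")
    for (f in c(genes, samples)) {
      if (!file.exists(f)) {
        cpc_abort(paste0("mtx sidecar file not found: ", f), "coordpc_io_error")
      }
    }
    m <- as.matrix(Matrix::readMM(path))
    gid <- readLines(genes)
    sid <- readLines(samples)
    if (nrow(m) != length(gid) || ncol(m) != length(sid)) {
      cpc_abort("mtx dimensions do not match sidecar ID counts",
                "coordpc_format_error")
    }
    tbl <- tibble::as_tibble(m, .name_repair = "minimal")
    names(tbl) <- sid
    tbl <- tibble::add_column(tbl, gene_id = gid, .before = 1)
  }
  validate_counts(tbl)
}

#' Write a counts table
#'
#' @param counts A counts tibble as returned by [read_counts()].
#' @param path Output path; `.mtx` triggers MatrixMarket output with
#'   `.genes.txt` / `.samples.txt` sidecars, anything else tab-separated text.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- Matrix::Matrix(expr_matrix(counts), sparse = TRUE)
    Matrix::writeMM(m, path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(counts$gene_id, paste0(stem, ".genes.txt"))
    writeLines(names(counts)[-1], paste0(stem, ".samples.txt"))
  } else {
    readr::write_tsv(counts, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a sample design table
#'
#' Tab-separated with columns `sample_id`, `group`, and optionally `cohort`.
#' Groups referenced by a correlation analysis need at least 3 samples;
#' fewer than 5 triggers a warning (Pearson estimates at such depth are
#' noisy -- the source study itself used n = 6 per age group).
#'
#' @param path Path to the design TSV.
#' @return A tibble with columns `sample_id`, `group` and, if present, `cohort`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    cpc_abort(paste0("design file not found: ", path), "coordpc_io_error")
  }
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(d))) {
    cpc_abort("design table must have columns sample_id and group",
              "coordpc_format_error")
  }
  if (anyDuplicated(d$sample_id)) {
    cpc_abort(paste0("duplicate sample_id in design: ",
                     d$sample_id[duplicated(d$sample_id)][1]))
  }
  d
}

#' Check a design against a counts table
#'
#' Verifies that every sample column of `counts` appears exactly once in the
#' design and that each group used has at least `min_n` samples.
#'
#' @param design Design tibble (see [read_design()]).
#' @param counts Counts tibble.
#' @param min_n Hard minimum group size (default 3; Pearson needs >= 3 points).
#' @return `design`, invisibly, filtered to the counts' samples.
#' @export
check_design <- function(design, counts, min_n = 3) {
  smp <- names(counts)[-1]
  missing <- setdiff(smp, design$sample_id)
  if (length(missing) > 0) {
    cpc_abort(paste0("samples absent from design: ",
                     paste(missing, collapse = ", ")))
  }
  design <- design[design$sample_id %in% smp, , drop = FALSE]
  sizes <- table(design$group)
  small <- names(sizes)[sizes < min_n]
  if (length(small) > 0) {
    cpc_abort(paste0("group(s) with fewer than ", min_n, " samples: ",
                     paste(small, collapse = ", ")))
  }
  low <- names(sizes)[sizes < 5]
  if (length(low) > 0) {
    warn(paste0("group(s) with fewer than 5 samples (correlations will be noisy): ",
                paste(low, collapse = ", ")))
  }
  invisible(design)
}

# Internal: validate the counts-tibble contract.
validate_counts <- function(counts, what = "counts", allow_negative = FALSE) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    cpc_abort(paste0(what, " must be a data frame: gene_id + >=1 sample column"))
  }
  counts <- tibble::as_tibble(counts)
  names(counts)[1] <- "gene_id"
  counts$gene_id <- as.character(counts$gene_id)
  if (nrow(counts) < 1) cpc_abort(paste0(what, " has no genes"))
  dup <- counts$gene_id[duplicated(counts$gene_id)]
  if (length(dup) > 0) {
    cpc_abort(paste0("duplicate gene_id: ", dup[1]))
  }
  dups <- names(counts)[-1][duplicated(names(counts)[-1])]
  if (length(dups) > 0) {
    cpc_abort(paste0("duplicate sample_id: ", dups[1]))
  }
  m <- as.matrix(counts[-1])
  if (!is.numeric(m) || anyNA(m)) {
    cpc_abort(paste0(what, " values must be numeric and non-missing"))
  }
  if (!allow_negative && any(m < 0)) cpc_abort(paste0(what, " values must be >= 0"))
  counts
}

# Internal: tibble (gene_id + samples) -> numeric matrix with gene rownames.
expr_matrix <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl$gene_id
  storage.mode(m) <- "double"
  m
}

# Internal: matrix with rownames -> tibble (gene_id first).
expr_tbl <- function(m) {
  tibble::add_column(tibble::as_tibble(m, .name_repair = "minimal"),
                     gene_id = rownames(m), .before = 1)
}
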