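# Shared manifest writer: inputs, file hashes, parameters, versions, seed.
write_manifest <- function(out_dir, step, params, files) {
  manifest <- list(
    step = step,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("coordpc")),
    r_version = R.version.string,
    params = params,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  out_dir
}

#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_coordination()] and writes `counts_young.tsv`,
#' `counts_old.tsv`, `design.tsv`, `truth.tsv` and a reproducibility
#' `manifest.json` (parameters, seed, file hashes) into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param params A [sim_params()] object.
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(out_dir, params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, as.list(params))
  ensure_dir(out_dir)
  sim <- simulate_coordination(params)
  files <- c(
    counts_young = file.path(out_dir, "counts_young.tsv"),
    counts_old = file.path(out_dir, "counts_old.tsv"),
    design = file.path(out_dir, "design.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_counts(sim$counts_young, files[["counts_young"]])
  write_counts(sim$counts_old, files[["counts_old"]])
  readr::write_tsv(sim$design, files[["design"]], progress = FALSE)
  readr::write_tsv(sim$truth, files[["truth"]], progress = FALSE)
  files["manifest"] <- write_manifest(out_dir, "simulate", unclass(params), files)
  invisible(files)
}

#' Run the Pc pipeline for one cohort
#'
#' Reads counts and a design table, splits samples into the two groups,
#' CPM-normalises, harmonises the gene universes, computes the composite
#' correlation index, and writes `pc_table.tsv` (gene_id, pc,
#' n_partners_used, status), `summary.json` (mean, median, % negative Pc,
#' genes analysed) and a manifest.
#'
#' Counts may be a single matrix covering both groups, or two matrices (one
#' per group) via `counts_old_path` when the conditions were quantified
#' separately.
#'
#' @param counts_path Counts file (TSV or MTX). With `counts_old_path` set,
#'   this holds the first (young) group only.
#' @param design_path Design TSV (`sample_id`, `group`).
#' @param out_dir Output directory.
#' @param counts_old_path Optional second counts file for the old group.
#' @param groups Length-2 character: the young and old group labels in the
#'   design (default `c("young", "old")`).
#' @param log_transform,pseudocount,min_mean_cpm Passed to [cpm_normalize()].
#' @param block_size Passed to [composite_pc()].
#' @return The `pc_fit`, invisibly, with attribute `files`.
#' @export
run_pc <- function(counts_path, design_path, out_dir,
                   counts_old_path = NULL, groups = c("young", "old"),
                   log_transform = FALSE, pseudocount = 1, min_mean_cpm = 0,
                   block_size = 1024) {
  ensure_dir(out_dir)
  design <- read_design(design_path)
  split_cols <- function(counts, label) {
    smp <- design$sample_id[design$group == label]
    smp <- intersect(names(counts)[-1], smp)
    if (length(smp) < 3) {
      cpc_abort(paste0("group '", label, "' has fewer than 3 samples in the counts"))
    }
    counts[, c("gene_id", smp)]
  }
  if (is.null(counts_old_path)) {
    counts <- read_counts(counts_path)
    check_design(design, counts)
    cy <- split_cols(counts, groups[1])
    co <- split_cols(counts, groups[2])
  } else {
    cy <- read_counts(counts_path)
    co <- read_counts(counts_old_path)
    cy <- split_cols(cy, groups[1])
    co <- split_cols(co, groups[2])
  }
  ey <- cpm_normalize(cy, log_transform = log_transform,
                      pseudocount = pseudocount, min_mean_cpm = min_mean_cpm)
  eo <- cpm_normalize(co, log_transform = log_transform,
                      pseudocount = pseudocount, min_mean_cpm = min_mean_cpm)
  h <- harmonize_genes(ey, eo, quiet = TRUE)
  fit <- composite_pc(h$a, h$b, block_size = block_size)

  files <- c(
    pc_table = file.path(out_dir, "pc_table.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  readr::write_tsv(tidy(fit), files[["pc_table"]], progress = FALSE)
  jsonlite::write_json(as.list(glance(fit)), files[["summary"]],
                       auto_unbox = TRUE, digits = NA)
  files["manifest"] <- write_manifest(
    out_dir, "pc",
    list(counts = counts_path, counts_old = counts_old_path,
         design = design_path, groups = groups,
         log_transform = log_transform, pseudocount = pseudocount,
         min_mean_cpm = min_mean_cpm, block_size = block_size),
    files
  )
  attr(fit, "files") <- files
  invisible(fit)
}

#' Read a Pc table written by [run_pc()]
#'
#' @param path Path to a `pc_table.tsv`.
#' @return A tibble `gene_id`, `pc`, `n_partners_used`, `status`.
#' @export
read_pc_table <- function(path) {
  if (!file.exists(path)) cpc_abort(paste0("Pc table not found: ", path), "coordpc_io_error")
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    pc = readr::col_double(),
    n_partners_used = readr::col_integer(),
    status = readr::col_character()
  ), progress = FALSE)
}

#' Compare two cohorts' Pc tables and write the report
#'
#' Runs [compare_cohorts()] (raw + size-normalised tests and quartile
#' report), [top_ranked()] in both directions, and [export_go_candidates()],
#' writing `report.json`, `report.txt`, `top_highest.tsv`, `top_lowest.tsv`
#' (per cohort) and `go_candidates_<label>.txt`.
#'
#' @param pc_a_path,pc_b_path Paths to `pc_table.tsv` files.
#' @param out_dir Output directory.
#' @param labels Cohort labels (default `c("a", "b")`).
#' @param k_top Ranking depth (default 10).
#' @param k_go GO-candidate list depth (default 500).
#' @param n_draws,seed,test Passed to [compare_cohorts()].
#' @return The `pc_comparison`, invisibly, with attribute `files`.
#' @export
run_compare <- function(pc_a_path, pc_b_path, out_dir, labels = c("a", "b"),
                        k_top = 10, k_go = 500, n_draws = 100, seed = 1,
                        test = "mann_whitney") {
  ensure_dir(out_dir)
  pcs <- list(read_pc_table(pc_a_path), read_pc_table(pc_b_path))
  cmp <- compare_cohorts(pcs[[1]], pcs[[2]], labels = labels,
                         n_draws = n_draws, seed = seed, test = test)
  files <- c(report = file.path(out_dir, "report.json"),
             report_txt = file.path(out_dir, "report.txt"))
  jsonlite::write_json(
    list(cohorts = cmp$cohorts, raw = as.list(cmp$raw),
         normalized = as.list(cmp$normalized),
         quartiles = cmp$quartiles,
         rankings = purrr::imap(setNames(pcs, labels), function(pc, lab) {
           list(highest = top_ranked(pc, k_top, "highest"),
                lowest = top_ranked(pc, k_top, "lowest"))
         }),
         meta = cmp$meta),
    files[["report"]], auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  writeLines(utils::capture.output(print(cmp)), files[["report_txt"]])
  for (i in 1:2) {
    lab <- labels[i]
    fh <- file.path(out_dir, paste0("top_highest_", lab, ".tsv"))
    fl <- file.path(out_dir, paste0("top_lowest_", lab, ".tsv"))
    fg <- file.path(out_dir, paste0("go_candidates_", lab, ".txt"))
    readr::write_tsv(top_ranked(pcs[[i]], k_top, "highest"), fh, progress = FALSE)
    readr::write_tsv(top_ranked(pcs[[i]], k_top, "lowest"), fl, progress = FALSE)
    export_go_candidates(pcs[[i]], fg, k = k_go)
    files[paste0(c("top_highest_", "top_lowest_", "go_candidates_"), lab)] <- c(fh, fl, fg)
  }
  files["manifest"] <- write_manifest(
    out_dir, "compare",
    list(pc_a = pc_a_path, pc_b = pc_b_path, labels = labels, k_top = k_top,
         k_go = k_go, n_draws = n_draws, seed = seed, test = test),
    files
  )
  attr(cmp, "files") <- files
  invisible(cmp)
}
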