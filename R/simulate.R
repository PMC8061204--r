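#' Parameters for the two-condition coordination simulator
#'
#' Defines a latent-Gaussian, negative-binomial count generator with modular
#' co-expression and a controllable fraction of genes whose coordination
#' profile inverts (or dissolves) between the two conditions. Defaults mirror
#' the study design the package targets: 6 samples per age group, a quarter
#' of the genes inverting (observed fractions in brain aging were 23-27%),
#' moderate within-module correlation, and bulk-RNA-seq-like counts.
#'
#' @param G Number of genes (>= 4). Default 400: large enough for stable Pc
#'   distributions, small enough for desk-scale runs.
#' @param S Samples per condition (>= 3). Default 6.
#' @param M Number of co-expression modules. Default 10, giving modules of
#'   ~G/M = 40 genes at the default G, the scale of typical co-expression
#'   modules.
#' @param rho Within-module latent correlation, in `[0, 1)`. Default 0.7.
#' @param f_invert Fraction of genes whose module loading flips sign in
#'   condition 2 (coordination inversion). Default 0.25.
#' @param f_decorrelate Fraction whose loading moves to a fresh, independent
#'   latent factor in condition 2 (coordination loss without inversion).
#'   Default 0. `f_invert + f_decorrelate` must not exceed 1.
#' @param noise_sd Extra per-gene independent latent noise SD. Default 0.1.
#' @param mean_log_expr Log-scale mean of counts. Default 5 (~150 reads).
#' @param disp Negative-binomial dispersion; 0 gives Poisson counts.
#'   Default 0.1, a typical bulk biological coefficient of dispersion.
#' @param seed Integer seed; identical parameters give identical datasets.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(G = 400, S = 6, M = 10, rho = 0.7,
                       f_invert = 0.25, f_decorrelate = 0,
                       noise_sd = 0.1, mean_log_expr = 5, disp = 0.1,
                       seed = 1) {
  p <- list(G = G, S = S, M = M, rho = rho, f_invert = f_invert,
            f_decorrelate = f_decorrelate, noise_sd = noise_sd,
            mean_log_expr = mean_log_expr, disp = disp, seed = seed)
  if (G < 4) cpc_abort("G must be >= 4")
  if (S < 3) cpc_abort("S must be >= 3")
  if (M < 1 || M > G) cpc_abort("M must be in [1, G]")
  if (rho < 0 || rho >= 1) cpc_abort("rho must be in [0, 1)")
  if (f_invert < 0 || f_decorrelate < 0 || f_invert + f_decorrelate > 1) {
    cpc_abort("need f_invert, f_decorrelate >= 0 and f_invert + f_decorrelate <= 1")
  }
  if (noise_sd < 0) cpc_abort("noise_sd must be >= 0")
  if (disp < 0) cpc_abort("disp must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1) cpc_abort("seed must be one integer")
  structure(p, class = "sim_params")
}

#' Cohort-style simulation presets
#'
#' Two presets emulating the qualitative contrast between a short-lived
#' cohort with a smaller gene universe but tighter, more drastic coordination
#' changes ("bw"), and a longer-lived cohort with a larger universe and
#' broader but subtler reorganisation ("ll"). The bw preset uses higher
#' within-module correlation and little decorrelation, producing a higher
#' median Pc and a wider Pc range (more strongly negative bottom quartile,
#' more strongly positive top quartile); the ll preset uses lower correlation
#' and more decorrelated genes, lowering the average Pc while compressing the
#' range. Inversion fractions (23% / 27%) follow the observed shares of
#' negative-Pc transcripts in the two cohorts.
#'
#' @param cohort `"bw"` or `"ll"`.
#' @param seed Integer seed.
#' @param scale Multiplier on the preset gene-universe sizes (default 1:
#'   desk-scale G of 300 and 400).
#' @return A `sim_params` object.
#' @export
cohort_preset <- function(cohort = c("bw", "ll"), seed = 1, scale = 1) {
  switch(match.arg(cohort),
    bw = sim_params(G = round(300 * scale), S = 6, M = max(2, round(8 * scale)),
                    rho = 0.8, f_invert = 0.23, f_decorrelate = 0.10,
                    seed = seed),
    ll = sim_params(G = round(400 * scale), S = 6, M = max(2, round(10 * scale)),
                    rho = 0.55, f_invert = 0.27, f_decorrelate = 0.30,
                    seed = seed)
  )
}

#' Simulate two-condition counts with known coordination structure
#'
#' Generative model: genes are assigned to `M` modules of (near-)equal size;
#' gene g loads on its module factor with loading `lambda_g = +/- sqrt(rho)`
#' (sign random, fixed per gene). For each sample, module factors and
#' per-gene noise are independent standard normals, giving latent
#' `z = lambda * factor + sqrt(1 - rho) * eps + noise_sd * eta`. In
#' condition 2, inverted genes use `-lambda` (their correlations with all
#' module partners flip sign), decorrelated genes load on a fresh independent
#' per-gene factor (their profile becomes orthogonal to the old one, not
#' anti-correlated), and retained genes keep `lambda`. Counts are drawn
#' negative-binomial with mean `exp(mean_log_expr + z)` and dispersion
#' `disp` (Poisson when `disp = 0`). All draws come from the seeded
#' generator, so identical parameters give identical datasets.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_dataset` list: `counts_young`, `counts_old` (counts
#'   tibbles), `truth` (tibble `gene_id`, `label` in
#'   retained/inverted/decorrelated, `module`), `design` (both conditions),
#'   and `params`.
#' @export
#' @examples
#' sim <- simulate_coordination(sim_params(G = 40, S = 6, M = 4, seed = 7))
#' dplyr::count(sim$truth, label)
simulate_coordination <- function(params) {
  if (!inherits(params, "sim_params")) {
    params <- do.call(sim_params, as.list(params))
  }
  p <- params
  with_local_seed(p$seed, {
    gene_id <- sprintf("G%05d", seq_len(p$G))
    module <- rep_len(seq_len(p$M), p$G)

    n_inv <- round(p$f_invert * p$G)
    n_dec <- round(p$f_decorrelate * p$G)
    label <- rep("retained", p$G)
    picked <- sample.int(p$G, n_inv + n_dec)
    label[picked[seq_len(n_inv)]] <- "inverted"
    if (n_dec > 0) label[picked[n_inv + seq_len(n_dec)]] <- "decorrelated"

    lambda <- sample(c(-1, 1), p$G, replace = TRUE) * sqrt(p$rho)

    latent <- function(load, fresh_factor_for = NULL) {
      fac <- matrix(rnorm(p$M * p$S), p$M, p$S)
      z <- load * fac[module, , drop = FALSE] +
        sqrt(1 - p$rho) * matrix(rnorm(p$G * p$S), p$G, p$S) +
        p$noise_sd * matrix(rnorm(p$G * p$S), p$G, p$S)
      if (!is.null(fresh_factor_for) && any(fresh_factor_for)) {
        k <- sum(fresh_factor_for)
        own <- matrix(rnorm(k * p$S), k, p$S)   # private factor per gene
        z[fresh_factor_for, ] <- load[fresh_factor_for] * own +
          sqrt(1 - p$rho) * matrix(rnorm(k * p$S), k, p$S) +
          p$noise_sd * matrix(rnorm(k * p$S), k, p$S)
      }
      z
    }
    draw_counts <- function(z, prefix) {
      mu <- exp(p$mean_log_expr + z)
      cts <- if (p$disp > 0) {
        rnbinom(length(mu), mu = mu, size = 1 / p$disp)
      } else {
        rpois(length(mu), mu)
      }
      m <- matrix(cts, p$G, p$S, dimnames = list(gene_id, paste0(prefix, seq_len(p$S))))
      expr_tbl(m)
    }

    zy <- latent(lambda)
    lambda_old <- lambda
    lambda_old[label == "inverted"] <- -lambda[label == "inverted"]
    zo <- latent(lambda_old, fresh_factor_for = label == "decorrelated")

    structure(
      list(
        counts_young = draw_counts(zy, "young_"),
        counts_old = draw_counts(zo, "old_"),
        truth = tibble::tibble(gene_id = gene_id, label = label, module = module),
        design = tibble::tibble(
          sample_id = c(paste0("young_", seq_len(p$S)), paste0("old_", seq_len(p$S))),
          group = rep(c("young", "old"), each = p$S)
        ),
        params = p
      ),
      class = "sim_dataset"
    )
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("<sim_dataset> G = %d genes x S = %d samples/condition, M = %d modules\n",
              p$G, p$S, p$M))
  cat(sprintf("  rho = %.2f, f_invert = %.2f, f_decorrelate = %.2f, seed = %s\n",
              p$rho, p$f_invert, p$f_decorrelate, format(p$seed)))
  print(dplyr::count(x$truth, .data$label))
  invisible(x)
}

#' Score Pc recovery against simulation truth
#'
#' Joins a Pc table with the generator's truth labels and reports the mean
#' and median Pc per class plus a rank-based separation score between the
#' retained and inverted classes: the probability that a random retained
#' gene's Pc exceeds a random inverted gene's (the Mann-Whitney AUC; 1 =
#' perfect separation, 0.5 = chance).
#'
#' @param pc A `pc_fit` or Pc tibble.
#' @param truth Truth tibble from [simulate_coordination()] (`gene_id`,
#'   `label`).
#' @return A list with `by_class` (tibble: label, n, mean_pc, median_pc) and
#'   `separation` (scalar AUC, `NA` if either class is absent).
#' @export
recovery_score <- function(pc, truth) {
  ok <- pc_values(pc)
  truth <- tibble::as_tibble(truth)
  joined <- dplyr::inner_join(ok, truth, by = "gene_id")
  if (nrow(joined) == 0) cpc_abort("Pc table and truth share no genes")
  by_class <- joined |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), mean_pc = mean(.data$pc),
                     median_pc = median(.data$pc), .groups = "drop")
  ret <- joined$pc[joined$label == "retained"]
  inv <- joined$pc[joined$label == "inverted"]
  sep <- if (length(ret) > 0 && length(inv) > 0) {
    r <- rank(c(ret, inv))
    u <- sum(r[seq_along(ret)]) - length(ret) * (length(ret) + 1) / 2
    u / (length(ret) * length(inv))
  } else {
    NA_real_
  }
  list(by_class = by_class, separation = sep)
}
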