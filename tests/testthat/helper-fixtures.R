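# Shared fixture builders and the independent full-matrix oracle.

# Random counts tibble with guaranteed per-gene variance.
random_counts <- function(G, S, seed = 1, prefix = "s") {
  withr::with_seed(seed, {
    m <- matrix(rpois(G * S, lambda = 50) + 1, G, S)
    m[, 1] <- m[, 1] + seq_len(G)   # no constant rows
    dimnames(m) <- list(sprintf("G%03d", seq_len(G)), paste0(prefix, seq_len(S)))
    tibble::add_column(tibble::as_tibble(m, .name_repair = "minimal"),
                       gene_id = rownames(m), .before = 1)
  })
}

# Naive Pc oracle: materialise both full G x G correlation matrices with
# stats::cor and correlate off-diagonal rows. Deliberately independent of the
# package's blocked crossproduct path.
naive_pc <- function(young, old) {
  my <- as.matrix(young[-1])
  mo <- as.matrix(old[-1])
  keep <- apply(my, 1, sd) > 0 & apply(mo, 1, sd) > 0
  my <- my[keep, , drop = FALSE]
  mo <- mo[keep, , drop = FALSE]
  ry <- cor(t(my))
  ro <- cor(t(mo))
  pc <- vapply(seq_len(nrow(ry)), function(i) cor(ry[i, -i], ro[i, -i]), 0)
  tibble::tibble(gene_id = young$gene_id[keep], pc = pc)
}

# Quick simulate -> CPM -> composite_pc for one parameter set.
fit_sim <- function(params) {
  sim <- simulate_coordination(params)
  fit <- composite_pc(cpm_normalize(sim$counts_young),
                      cpm_normalize(sim$counts_old))
  list(sim = sim, fit = fit)
}
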