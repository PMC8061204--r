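test_that("pearson_r matches closed-form cases and flags degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(pearson_r(c(1, 2, 3), c(5, 5, 5))))
  expect_true(is.na(pearson_r(c(4, 4, 4), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("correlation profiles reproduce hand-computed Pearson values", {
  expr <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    !!!setNames(as.data.frame(t(matrix(c(
      1, 2, 3, 4, 5, 6,
      2, 4, 6, 8, 10, 12,
      6, 5, 4, 3, 2, 1,
      1, 3, 2, 5, 4, 6
    ), nrow = 6))), paste0("s", 1:6))
  )
  prof <- correlation_profiles(expr)
  pa <- dplyr::filter(prof, gene_id == "A")
  expect_equal(pa$partner_id, c("B", "C", "D"))
  expect_equal(pa$r[pa$partner_id == "B"], 1)
  expect_equal(pa$r[pa$partner_id == "C"], -1)
  # direct product-moment formula, computed by hand from the raw vectors
  x <- c(1, 2, 3, 4, 5, 6); y <- c(1, 3, 2, 5, 4, 6)
  r_ad <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pa$r[pa$partner_id == "D"], r_ad)

  # every profile excludes the focal gene: length G_analyzed - 1
  expect_true(all(table(prof$gene_id) == nrow(expr) - 1))
  expect_false(any(prof$gene_id == prof$partner_id))
})

test_that("profiles are independent of block size and of gene order", {
  expr <- cpm_normalize(random_counts(G = 17, S = 6, seed = 4))
  p1 <- correlation_profiles(expr, block_size = 1)
  pG <- correlation_profiles(expr, block_size = nrow(expr))
  expect_equal(p1, pG)

  perm <- withr::with_seed(1, sample(nrow(expr)))
  pp <- correlation_profiles(expr[perm, ], block_size = 5)
  joined <- dplyr::inner_join(p1, pp, by = c("gene_id", "partner_id"),
                              suffix = c("", "_perm"))
  expect_equal(nrow(joined), nrow(p1))
  expect_equal(joined$r, joined$r_perm)
})

test_that("blocked composite_pc equals the naive full-matrix oracle", {
  for (seed in 1:5) {
    G <- withr::with_seed(seed, sample(10:50, 1))
    young <- cpm_normalize(random_counts(G = G, S = 6, seed = seed))
    old <- cpm_normalize(random_counts(G = G, S = 6, seed = seed + 100))
    fit <- composite_pc(young, old, block_size = 7)
    oracle <- naive_pc(young, old)
    expect_equal(tidy(fit)$pc, oracle$pc, tolerance = 1e-10)
    expect_equal(tidy(fit)$n_partners_used, rep(G - 1L, G))
  }
})

test_that("identical conditions give Pc = 1; a mean-reflected gene gives Pc = -1", {
  expr <- cpm_normalize(random_counts(G = 12, S = 6, seed = 6))
  fit <- composite_pc(expr, expr)
  expect_equal(tidy(fit)$pc, rep(1, 12))

  # reflect one gene's expression about its mean in the old condition only
  old <- expr
  i <- 5
  g <- expr$gene_id[i]
  row <- as.numeric(old[i, -1])
  old[i, -1] <- as.list(2 * mean(row) - row)
  fit2 <- composite_pc(expr, old)
  expect_equal(tidy(fit2)$pc[i], -1)

  # every correlation of the reflected gene flips sign; all other gene-pair
  # correlations are untouched
  py <- correlation_profiles(expr)
  po <- correlation_profiles(old)
  joined <- dplyr::inner_join(py, po, by = c("gene_id", "partner_id"),
                              suffix = c("_y", "_o"))
  touches_g <- joined$gene_id == g | joined$partner_id == g
  expect_equal(joined$r_o[touches_g], -joined$r_y[touches_g])
  expect_equal(joined$r_o[!touches_g], joined$r_y[!touches_g])

  # other genes' Pc only moves through their single flipped partner entry:
  # with that partner excluded their profiles still match exactly
  for (j in c(1, 8)) {
    pj <- gene_r_profiles(expr, old, expr$gene_id[j])
    pj <- pj[pj$partner_id != g, ]
    expect_equal(pj$r_young, pj$r_old)
  }
})

test_that("Pc is affine-invariant and flips sign under one-sided negation", {
  young <- cpm_normalize(random_counts(G = 10, S = 6, seed = 7))
  old <- cpm_normalize(random_counts(G = 10, S = 6, seed = 77))
  base <- tidy(composite_pc(young, old))

  # y -> a*y + b (a > 0) on one gene in both conditions: nothing changes
  y2 <- young; o2 <- old
  y2[3, -1] <- as.list(2.5 * as.numeric(y2[3, -1]) + 10)
  o2[3, -1] <- as.list(2.5 * as.numeric(o2[3, -1]) + 10)
  expect_equal(tidy(composite_pc(y2, o2))$pc, base$pc)

  # a < 0 in only one condition flips that gene's Pc exactly
  o3 <- old
  o3[3, -1] <- as.list(-1 * as.numeric(o3[3, -1]) + 50)
  flipped <- tidy(composite_pc(young, o3))
  expect_equal(flipped$pc[3], -base$pc[3])

  # a < 0 applied in BOTH conditions cancels for the focal gene itself
  y3 <- young
  y3[3, -1] <- as.list(-1 * as.numeric(y3[3, -1]) + 50)
  expect_equal(tidy(composite_pc(y3, o3))$pc[3], base$pc[3])
})

test_that("sample permutation changes nothing; gene permutation permutes rows", {
  young <- cpm_normalize(random_counts(G = 9, S = 6, seed = 8))
  old <- cpm_normalize(random_counts(G = 9, S = 6, seed = 88))
  base <- tidy(composite_pc(young, old))

  perm_s <- c(1, 4, 2, 6, 5, 3)
  young_p <- young[, c(1, 1 + perm_s)]
  expect_equal(tidy(composite_pc(young_p, old))$pc, base$pc)

  perm_g <- withr::with_seed(2, sample(9))
  permuted <- tidy(composite_pc(young[perm_g, ], old[perm_g, ]))
  expect_equal(permuted$gene_id, base$gene_id[perm_g])
  expect_equal(permuted$pc, base$pc[perm_g])
})

test_that("zero-variance genes are flagged and excluded as partners", {
  young <- cpm_normalize(random_counts(G = 8, S = 6, seed = 10))
  old <- cpm_normalize(random_counts(G = 8, S = 6, seed = 11))
  # gene 2 constant in young, gene 5 constant in old (pre-CPM constancy is
  # destroyed by library scaling, so set it after normalisation)
  young[2, -1] <- as.list(rep(100, 6))
  old[5, -1] <- as.list(rep(40, 6))
  fit <- composite_pc(young, old)
  tbl <- tidy(fit)
  expect_equal(tbl$status[2], "zero_variance_young")
  expect_equal(tbl$status[5], "zero_variance_old")
  expect_true(all(is.na(tbl$pc[c(2, 5)])))
  # remaining genes use only the 5 other analysable partners
  expect_equal(tbl$n_partners_used[tbl$status == "ok"], rep(5L, 6))
  # and agree with the oracle computed on the analysable universe
  oracle <- naive_pc(young, old)
  expect_equal(tbl$pc[tbl$status == "ok"], oracle$pc, tolerance = 1e-10)
  expect_equal(fit$meta$g_analyzed, 6)
})

test_that("defined Pc values always stay inside [-1, 1]", {
  for (seed in 1:10) {
    G <- withr::with_seed(seed, sample(8:30, 1))
    young <- cpm_normalize(random_counts(G = G, S = 5, seed = seed * 13))
    old <- cpm_normalize(random_counts(G = G, S = 5, seed = seed * 13 + 1))
    pc <- tidy(composite_pc(young, old))$pc
    expect_true(all(abs(pc[!is.na(pc)]) <= 1))
  }
})

test_that("gene_r_profiles returns aligned vectors consistent with the fit", {
  young <- cpm_normalize(random_counts(G = 14, S = 6, seed = 21))
  old <- cpm_normalize(random_counts(G = 14, S = 6, seed = 22))
  fit <- composite_pc(young, old)
  g <- "G007"
  prof <- gene_r_profiles(young, old, g)
  expect_equal(nrow(prof), tidy(fit)$n_partners_used[tidy(fit)$gene_id == g])
  expect_equal(cor(prof$r_young, prof$r_old),
               tidy(fit)$pc[tidy(fit)$gene_id == g])
  # identical matrices: the two vectors coincide
  same <- gene_r_profiles(young, young, g)
  expect_equal(same$r_young, same$r_old)
  # oracle check on the medians of the two vectors
  my <- as.matrix(young[-1]); ry <- cor(t(my))
  i <- match(g, young$gene_id)
  expect_equal(median(prof$r_young), median(ry[i, -i]))
  expect_error(gene_r_profiles(young, old, "nope"), "unknown gene")
})

test_that("input guards reject unusable matrices", {
  small <- cpm_normalize(random_counts(G = 4, S = 3, seed = 1))
  two_samples <- small[, 1:3]
  expect_error(composite_pc(two_samples, two_samples), "at least 3 samples")
  expect_error(composite_pc(small[1:3, ], small[1:3, ]), "at least 4 genes")
  const <- small
  for (i in 1:4) const[i, -1] <- as.list(rep(i, 3))
  expect_error(composite_pc(const, small), "non-zero variance")
  reordered <- small[c(2, 1, 3, 4), ]
  expect_error(composite_pc(small, reordered), "identical, ordered gene universe")
})
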