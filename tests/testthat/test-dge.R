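mk_counts <- function(m, genes = sprintf("g%03d", seq_len(nrow(m)))) {
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

two_groups <- function(samples) {
  tibble::tibble(sample_id = samples,
                 group = rep(c("control", "treated"), each = length(samples) / 2))
}

test_that("the CPM filter removes low-count genes as specified", {
  m <- matrix(100L, nrow = 4, ncol = 4,
              dimnames = list(NULL, c("c1", "c2", "t1", "t2")))
  m[1, ] <- 0L                      # all-zero gene
  lib_target <- 2e6
  m[2, ] <- 1L                      # will sit at CPM 0.5 once libs ~ 2e6
  m[3, ] <- 4L                      # CPM ~ 2 everywhere
  m[4, ] <- as.integer(lib_target - colSums(m[1:3, , drop = FALSE]))
  counts <- mk_counts(m)
  stopifnot(all(colSums(m) == lib_target))

  kept <- cpm_filter(counts, two_groups(colnames(m)))
  expect_false("g001" %in% kept$gene_id)  # zero everywhere
  expect_false("g002" %in% kept$gene_id)  # CPM 0.5 < 1
  expect_true("g003" %in% kept$gene_id)   # CPM >= 1 in all samples
  expect_true("g004" %in% kept$gene_id)

  expect_error(cpm_filter(mk_counts(matrix(0L, 2, 4,
                                           dimnames = list(NULL, colnames(m)))),
                          two_groups(colnames(m))),
               class = "protoselect_config_error")
})

test_that("TMM factors behave as the trimmed-mean definition demands", {
  set.seed(71)
  m <- matrix(rpois(2000, 100), nrow = 500, ncol = 4,
              dimnames = list(NULL, c("c1", "c2", "t1", "t2")))

  # identical samples: all factors exactly 1
  ident <- m
  ident[, ] <- m[, 1]
  f_ident <- tmm_factors(mk_counts(ident))
  expect_equal(f_ident$factor, rep(1, 4))

  # uniformly doubling one library changes its size, not its factor
  doubled <- m
  doubled[, 2] <- m[, 2] * 2L
  f_doub <- tmm_factors(mk_counts(doubled))
  expect_lt(abs(f_doub$factor[2] - 1), 0.02)

  # geometric mean of factors is 1 by construction
  expect_lt(abs(prod(f_doub$factor)^(1 / 4) - 1), 1e-9)

  expect_error(tmm_factors(mk_counts(matrix(0L, 3, 4,
                                            dimnames = list(NULL, colnames(m))))),
               class = "protoselect_config_error")
})

test_that("TMM matches the reference edgeR implementation", {
  skip_if_not_installed("edgeR")
  cfg <- simulation_config(seed = 72, n_genes_expr = 1000,
                           n_samples_per_group = 4)
  sc <- simulate_counts(cfg)
  filtered <- cpm_filter(sc$counts, sc$groups)
  ours <- tmm_factors(filtered)
  m <- as.matrix(filtered[, -1])
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(ours$factor, unname(theirs), tolerance = 1e-8)
})

test_that("the exact NB test controls the null and obeys the contract", {
  cfg <- simulation_config(seed = 73, n_genes_expr = 2000,
                           n_samples_per_group = 5,
                           planted_log2fc = setNames(numeric(), character()))
  sc <- simulate_counts(cfg)
  filtered <- cpm_filter(sc$counts, sc$groups)
  fit <- test_de(filtered, sc$groups)
  tbl <- tidy(fit)

  # identical-distribution groups: near-uniform p-values, ~no calls
  ks <- suppressWarnings(stats::ks.test(tbl$pvalue, "punif"))$statistic
  expect_lt(unname(ks), 0.1)
  expect_lte(sum(tbl$significant), 2L)

  # significance contract on every row
  expect_identical(tbl$significant,
                   abs(tbl$log2fc) >= 1 & tbl$fdr <= 0.05)
  expect_true(all(tbl$fdr >= tbl$pvalue))
})

test_that("log2 fold changes flip sign exactly when labels swap", {
  cfg <- simulation_config(seed = 74, n_genes_expr = 300,
                           n_samples_per_group = 3)
  sc <- simulate_counts(cfg)
  filtered <- cpm_filter(sc$counts, sc$groups)
  fit <- test_de(filtered, sc$groups)
  swapped <- sc$groups
  swapped$group <- ifelse(swapped$group == "control", "treated", "control")
  fit_sw <- test_de(filtered, swapped)
  expect_equal(tidy(fit_sw)$log2fc, -tidy(fit)$log2fc)
  expect_equal(tidy(fit_sw)$pvalue, tidy(fit)$pvalue)
})

test_that("planted fold changes are detected with calibrated error control", {
  cfg <- simulation_config(seed = 75, n_genes_expr = 2000,
                           n_samples_per_group = 5, nb_dispersion = 0.1)
  sc <- simulate_counts(cfg)
  filtered <- cpm_filter(sc$counts, sc$groups)
  fit <- test_de(filtered, sc$groups)
  tbl <- tidy(fit)
  truth <- sc$truth
  called <- tbl$gene_id[tbl$significant]
  de <- truth$gene_id[truth$is_de]
  expect_gte(mean(de %in% called), 0.8)          # power
  expect_lte(mean(!(called %in% de)), 0.1)       # false discovery fraction
  g <- glance(fit)
  expect_identical(g$n_significant, g$n_up + g$n_down)
})
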