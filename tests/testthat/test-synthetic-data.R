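test_that("config validation rejects malformed worlds", {
  expect_error(simulation_config(substitution_rates = c(0.5, 1.2)),
               class = "protoselect_config_error")
  expect_error(simulation_config(nb_dispersion = -0.1),
               class = "protoselect_config_error")
  expect_error(simulation_config(n_samples_per_group = 1),
               class = "protoselect_config_error")
  expect_error(
    simulation_config(n_strains = 2, strain_mixtures = list(c(strain_01 = 0.6,
                                                              strain_02 = 0.3))),
    class = "protoselect_config_error"
  )
})

test_that("genome simulation follows the neutral substitution model", {
  # zero rates: every genome equals the ancestor, expected identity all 1
  cfg0 <- simulation_config(seed = 2, n_strains = 3, genome_length = 6000,
                            substitution_rates = 0, n_contigs = 1)
  sim0 <- simulate_genomes(cfg0)
  for (ctg in sim0$genomes$contigs) {
    expect_identical(unname(ctg[[1]]), sim0$truth$ancestor)
  }
  expect_true(all(sim0$truth$expected_identity == 1))

  # rates {0, 0.01}: expected identity exactly 0.99, empirical within 3 sigma
  cfg <- simulation_config(seed = 3, n_strains = 2, genome_length = 20000,
                           substitution_rates = c(0, 0.01), n_contigs = 1)
  sim <- simulate_genomes(cfg)
  expect_equal(sim$truth$expected_identity["strain_01", "strain_02"], 0.99)
  n_mut <- length(sim$truth$substitution_positions$strain_02)
  sigma <- sqrt(20000 * 0.01 * 0.99)
  expect_lt(abs(n_mut - 200), 3 * sigma)

  # rates above 0.3 break the identity model and are rejected
  expect_error(
    simulate_genomes(simulation_config(substitution_rates = 0.35)),
    class = "protoselect_rate_error"
  )
})

test_that("generators are byte-deterministic given the master seed", {
  cfg <- simulation_config(seed = 5, n_strains = 3, genome_length = 6000,
                           n_samples = 2, reads_per_sample = 200,
                           n_core_families = 4, n_genes_expr = 50)
  a <- simulate_genomes(cfg)
  b <- simulate_genomes(cfg)
  expect_identical(a, b)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genomes(a$genomes, d1)
  write_genomes(b$genomes, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  expect_identical(simulate_metagenome(cfg, a$genomes),
                   simulate_metagenome(cfg, b$genomes))
  expect_identical(simulate_proteomes(cfg), simulate_proteomes(cfg))
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
})

test_that("metagenome reads honour the configured mixtures", {
  # single-strain, error-free: every read is an exact genome substring
  cfg <- simulation_config(seed = 7, n_strains = 2, genome_length = 6000,
                           n_contigs = 2, n_samples = 1,
                           reads_per_sample = 50, read_length = 100,
                           read_error_rate = 0,
                           strain_mixtures = list(c(strain_01 = 1.0)))
  sim <- simulate_genomes(cfg)
  mg <- simulate_metagenome(cfg, sim$genomes)
  g1 <- sim$genomes$contigs[[1]]
  for (rd in mg$samples$reads[[1]]) {
    expect_true(any(vapply(g1, function(ctg) grepl(rd, ctg, fixed = TRUE),
                           logical(1))))
  }

  # zero reads: empty but valid sample
  cfg0 <- simulation_config(seed = 7, n_strains = 2, genome_length = 6000,
                            n_samples = 1, reads_per_sample = 0)
  mg0 <- simulate_metagenome(cfg0, sim$genomes)
  expect_length(mg0$samples$reads[[1]], 0)
  d <- withr::local_tempdir()
  write_samples(mg0$samples, d)
  expect_identical(readLines(file.path(d, "sample_001.fastq")), character(0))

  # 50/50 mixture over 10,000 reads: counts within 3 sigma of binomial
  cfg5 <- simulation_config(seed = 8, n_strains = 2, genome_length = 6000,
                            n_samples = 1, reads_per_sample = 10000,
                            read_length = 100,
                            strain_mixtures = list(c(strain_01 = 0.5,
                                                     strain_02 = 0.5)))
  mg5 <- simulate_metagenome(cfg5, sim$genomes)
  n1 <- mg5$truth$composition$n_reads[
    mg5$truth$composition$strain_id == "strain_01"]
  expect_lt(abs(n1 - 5000), 3 * sqrt(10000 * 0.25))

  # abundances must sum to one
  bad <- simulation_config(seed = 8, n_strains = 2, genome_length = 6000)
  bad$strain_mixtures <- list(c(strain_01 = 0.6, strain_02 = 0.3))
  bad$n_samples <- 1L
  expect_error(simulate_metagenome(bad, sim$genomes),
               class = "protoselect_config_error")
})

test_that("proteome simulation plants the promised family structure", {
  cfg <- simulation_config(seed = 9, n_strains = 4, n_core_families = 6,
                           n_accessory_families = 3,
                           planted_unique = c(strain_02 = 5),
                           protein_length_range = c(50, 120))
  pr <- simulate_proteomes(cfg)
  tr <- pr$truth

  # exactly 5 focal proteins with no family co-members
  fam_sizes <- table(tr$family_id)
  singletons <- names(fam_sizes)[fam_sizes == 1]
  solo <- tr[tr$family_id %in% singletons, ]
  expect_identical(sum(solo$strain_id == "strain_02" & solo$class == "unique"), 5L)

  # core families span all strains; accessory span 2..n-1
  core <- tr[tr$class == "core", ]
  expect_true(all(table(core$family_id) == 4L))
  acc <- tr[tr$class == "accessory", ]
  expect_true(all(table(acc$family_id) >= 2 & table(acc$family_id) <= 3))

  # zero divergence: core copies are identical across strains
  cfg0 <- simulation_config(seed = 9, n_strains = 3, n_core_families = 4,
                            n_accessory_families = 0,
                            planted_unique = setNames(integer(), character()),
                            protein_divergence = 0)
  pr0 <- simulate_proteomes(cfg0)
  merged <- merge(pr0$proteomes, pr0$truth, by = c("strain_id", "protein_id"))
  expect_true(all(tapply(merged$seq, merged$family_id,
                         function(x) length(unique(x)) == 1L)))

  # 2 strains, 9 core + 1 unique each: 20 proteins, 11 families
  cfg2 <- simulation_config(seed = 10, n_strains = 2, n_core_families = 9,
                            n_accessory_families = 0,
                            planted_unique = c(strain_01 = 1L, strain_02 = 1L))
  pr2 <- simulate_proteomes(cfg2)
  expect_identical(nrow(pr2$proteomes), 20L)
  expect_identical(length(unique(pr2$truth$family_id)), 11L)
})

test_that("count simulation matches its negative binomial model", {
  # no planted effects: truth is all-null
  cfg0 <- simulation_config(seed = 12, n_genes_expr = 100,
                            planted_log2fc = setNames(numeric(), character()))
  sc0 <- simulate_counts(cfg0)
  expect_false(any(sc0$truth$is_de))

  # dispersion -> 0 gives the Poisson limit: variance tracks the mean
  cfgp <- simulation_config(seed = 13, n_genes_expr = 1000,
                            n_samples_per_group = 10, nb_dispersion = 0,
                            planted_log2fc = setNames(numeric(), character()))
  scp <- simulate_counts(cfgp)
  m <- as.matrix(scp$counts[, -1])
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(mean(ratio) - 1), 0.05)

  # planted log2fc = 2 at baseline 100, n = 5: group mean ratio near 4
  cfg2 <- simulation_config(seed = 14, n_genes_expr = 500,
                            n_samples_per_group = 5, nb_dispersion = 0.1,
                            planted_log2fc = setNames(rep(2, 50),
                                                      sprintf("gene_%04d", 1:50)))
  sc2 <- simulate_counts(cfg2)
  m2 <- as.matrix(sc2$counts[, -1])
  ctrl <- rowMeans(m2[1:50, 1:5])
  trt <- rowMeans(m2[1:50, 6:10])
  expect_gt(median(trt / ctrl), 3)
  expect_lt(median(trt / ctrl), 5.3)
})
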