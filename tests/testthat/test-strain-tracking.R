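test_that("k-mer database enumerates canonical windows exactly", {
  g <- genome_tbl(s1 = "ACGTACGTA")
  db <- build_kmer_db(g, k = 5)
  # hand enumeration of the 5 windows, canonicalized via the Biostrings oracle
  windows <- substring("ACGTACGTA", 1:5, 5:9)
  expected <- unique(vapply(windows, canon_kmer_oracle, ""))
  expect_setequal(db$kmers$s1, expected)
  expect_lte(length(db$kmers$s1), 5L)

  # identical genomes index identically; N windows are skipped
  g2 <- genome_tbl(a = "ACGTACGTAACGTTGCA", b = "ACGTACGTAACGTTGCA")
  db2 <- build_kmer_db(g2, k = 5)
  expect_identical(db2$kmers$a, db2$kmers$b)

  gN <- genome_tbl(n = strrep("N", 50))
  expect_error(build_kmer_db(gN, k = 5),
               class = "protoselect_empty_kmer_set")
  expect_error(build_kmer_db(g, k = 4), class = "protoselect_config_error")
  expect_error(build_kmer_db(g, k = 11), class = "protoselect_config_error")
})

test_that("winner-takes-all detection finds exactly the present strains", {
  cfg <- simulation_config(seed = 41, n_strains = 4, genome_length = 8000,
                           substitution_rates = c(0.001, 0.008, 0.015, 0.022),
                           n_samples = 1, reads_per_sample = 400,
                           read_length = 100, read_error_rate = 0,
                           strain_mixtures = list(c(strain_02 = 1.0)))
  sim <- simulate_genomes(cfg)
  mg <- simulate_metagenome(cfg, sim$genomes)
  db <- build_kmer_db(sim$genomes)

  det <- detect_strains(db, mg$samples$reads[[1]], sample_id = "s1")
  expect_identical(det$strain_id, "strain_02")
  expect_identical(det$iteration, 1L)
  expect_gte(det$score, 0.1)

  # empty sample: empty detection table, not an error
  expect_identical(nrow(detect_strains(db, character())), 0L)

  # determinism
  expect_identical(det, detect_strains(db, mg$samples$reads[[1]],
                                       sample_id = "s1"))
})

test_that("adding reads from a strain never lowers its first-round score", {
  cfg <- simulation_config(seed = 42, n_strains = 3, genome_length = 6000,
                           n_samples = 2, reads_per_sample = 300,
                           read_length = 100, read_error_rate = 0,
                           strain_mixtures = list(c(strain_01 = 1.0),
                                                  c(strain_03 = 1.0)))
  sim <- simulate_genomes(cfg)
  mg <- simulate_metagenome(cfg, sim$genomes)
  db <- build_kmer_db(sim$genomes)
  base_reads <- mg$samples$reads[[2]]
  first_score <- function(reads) {
    km <- unique(canonical_kmers(reads, db$k))
    sum(db$kmers$strain_01 %in% km) / length(db$kmers$strain_01)
  }
  s0 <- first_score(base_reads)
  s1 <- first_score(c(base_reads, mg$samples$reads[[1]]))
  expect_gte(s1, s0)
})

test_that("prevalence is the per-sample binary detection fraction", {
  det <- tibble::tibble(
    sample_id = c("s1", "s2", "s1"),
    strain_id = c("a", "a", "b"),
    score = c(0.9, 0.8, 0.4),
    iteration = c(1L, 1L, 2L)
  )
  pv <- prevalence(det, 4, strain_ids = c("a", "b", "c"))
  expect_equal(pv$prevalence, c(0.5, 0.25, 0))

  # repeated detections in one sample count once
  det_dup <- dplyr::bind_rows(det, det[1, ])
  expect_equal(prevalence(det_dup, 4, strain_ids = c("a", "b", "c")),
               pv)

  expect_error(prevalence(det, 4, sample_ids = c("s1")),
               class = "protoselect_unknown_id")
})

test_that("AxP is mean ANI x prevalence x 100 with deterministic ranking", {
  ani <- tibble::tibble(query_id = c("a", "a", "b"),
                        ref_id = c("b", "c", "c"),
                        ani = c(0.98, 0.98, 0.96))
  pv <- tibble::tibble(strain_id = c("a", "b", "c"),
                       n_detected = c(2L, 0L, 4L),
                       prevalence = c(0.5, 0, 1))
  ax <- axp_rank(ani, pv)
  expect_equal(ax$axp[ax$strain_id == "a"], 0.98 * 0.5 * 100)
  expect_equal(ax$axp[ax$strain_id == "b"], 0)  # prevalence 0 regardless of ANI
  expect_equal(ax$axp[ax$strain_id == "c"], 0.97 * 1 * 100)
  expect_identical(ax$strain_id[1], "c")
  expect_identical(ax$rank, 1:3)

  # maximum of the index
  ani1 <- tibble::tibble(query_id = "x", ref_id = "y", ani = 1)
  pv1 <- tibble::tibble(strain_id = c("x", "y"), n_detected = c(2L, 2L),
                        prevalence = c(1, 1))
  expect_equal(axp_rank(ani1, pv1)$axp, c(100, 100))

  # ranking is invariant under rescaling all prevalences
  pv_scaled <- pv
  pv_scaled$prevalence <- pv$prevalence * 0.37
  expect_identical(axp_rank(ani, pv)$strain_id,
                   axp_rank(ani, pv_scaled)$strain_id)

  # strains absent from the ANI table are an error
  expect_error(
    axp_rank(ani[1, ], tibble::tibble(strain_id = c("a", "b", "z"),
                                      n_detected = 0L, prevalence = 0)),
    class = "protoselect_unknown_id"
  )
})
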