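# Shared simulated worlds, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- force(expr)
  .world_cache[[key]]
}

# small selection world: 4 public strains + 2 biobank strains, the biobank
# strain "strain_05" planted closest to the most central public strain
selection_world <- function() {
  cached("selection", {
    cfg <- simulation_config(
      seed = 421, n_strains = 6, genome_length = 8000,
      substitution_rates = c(0.001, 0.013, 0.025, 0.037, 0.003, 0.049),
      source = c(rep("public", 4), "biobank", "biobank"),
      n_samples = 4, reads_per_sample = 500, read_length = 100,
      read_error_rate = 0,
      strain_mixtures = list(
        c(strain_01 = 0.6, strain_02 = 0.4),
        c(strain_01 = 0.7, strain_03 = 0.3),
        c(strain_01 = 1.0),
        c(strain_01 = 0.5, strain_04 = 0.5)
      ),
      n_core_families = 8, n_accessory_families = 3,
      planted_unique = c(strain_01 = 2),
      protein_length_range = c(60, 140)
    )
    sim <- simulate_genomes(cfg)
    mg <- simulate_metagenome(cfg, sim$genomes[sim$genomes$source == "public", ])
    pr <- simulate_proteomes(cfg)
    list(cfg = cfg, genomes = sim$genomes, genome_truth = sim$truth,
         samples = mg$samples, sample_truth = mg$truth,
         proteomes = pr$proteomes, proteome_truth = pr$truth)
  })
}

selection_report_cached <- function() {
  cached("selection_report", {
    w <- selection_world()
    run_selection(w$genomes, w$samples, w$proteomes)
  })
}

# planted pangenome world for clustering tests
pangenome_world <- function(seed = 7) {
  cfg <- simulation_config(
    seed = seed, n_strains = 3, n_core_families = 8,
    n_accessory_families = 3, planted_unique = c(strain_01 = 3),
    protein_length_range = c(60, 150)
  )
  simulate_proteomes(cfg)
}
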