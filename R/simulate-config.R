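#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the four generators ([simulate_genomes()],
#' [simulate_metagenome()], [simulate_proteomes()], [simulate_counts()]) with
#' defaults chosen to emulate the statistical structure the downstream
#' analysis assumes: a within-species genome set whose pairwise ANI sits in
#' the 97.5-99.9% band typical of conspecific bacterial isolates, fecal
#' metagenome samples carrying a couple of database strains each, proteomes
#' with core/accessory/unique gene families, and negative binomial RNA-seq
#' counts from a two-condition triplicate design.
#'
#' @param seed Master seed. Each generator derives its own stream from it by
#'   a fixed offset (+101 genomes, +202 metagenomes, +303 proteomes, +404
#'   counts) so stages are individually reproducible.
#' @param genome_length Ancestor genome length in bp.
#' @param n_strains Number of strains derived from the common ancestor.
#' @param substitution_rates Per-strain substitution fraction relative to the
#'   ancestor, in `[0, 0.3]`. Default: evenly spaced over 0.001-0.012,
#'   giving pairwise identities between roughly 0.976 and 0.998.
#' @param indel_rate Per-site single-base indel fraction (split evenly
#'   between insertions and deletions). Default 0 so the closed-form
#'   expected-identity bookkeeping stays exact.
#' @param n_contigs Number of contigs each simulated assembly is split into.
#' @param coverage Sequencing coverage metadata attached to every genome
#'   (single value or one per strain).
#' @param source Source label attached to every genome (`"public"` or
#'   `"biobank"`; single value or one per strain).
#' @param n_samples Number of metagenome samples.
#' @param strain_mixtures Optional list (one element per sample) of named
#'   abundance vectors over strain ids, each summing to 1. `NULL` draws a
#'   random two-strain mixture per sample.
#' @param reads_per_sample,read_length,read_error_rate Read simulation
#'   parameters; errors are uniform substitutions at `read_error_rate` per
#'   base.
#' @param n_core_families Gene families present in every strain.
#' @param n_accessory_families Gene families present in a random proper
#'   subset of strains (at least 2, not all).
#' @param planted_unique Named integer vector, strain id -> number of gene
#'   families present in that strain only. Default plants 5 unique families
#'   in the first strain.
#' @param protein_length_range Length range (amino acids) for simulated
#'   proteins.
#' @param protein_divergence Per-residue substitution fraction applied
#'   independently to each strain's copy of a family ancestor.
#' @param n_genes_expr Number of genes in the simulated count matrix.
#' @param n_samples_per_group Replicates per condition (default 3, a typical
#'   in vitro triplicate design).
#' @param nb_dispersion Negative binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param planted_log2fc Named numeric vector, gene id -> planted log2 fold
#'   change applied to the treated group mean. Default plants +2 in genes
#'   1-50 and -2 in genes 51-100.
#' @param baseline_mean Mean count per gene in the control condition.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 20000L,
                              n_strains = 10L,
                              substitution_rates = NULL,
                              indel_rate = 0,
                              n_contigs = 3L,
                              coverage = 100,
                              source = "public",
                              n_samples = 20L,
                              strain_mixtures = NULL,
                              reads_per_sample = 2000L,
                              read_length = 150L,
                              read_error_rate = 0.001,
                              n_core_families = 20L,
                              n_accessory_families = 10L,
                              planted_unique = NULL,
                              protein_length_range = c(80L, 400L),
                              protein_divergence = 0.02,
                              n_genes_expr = 2000L,
                              n_samples_per_group = 3L,
                              nb_dispersion = 0.1,
                              planted_log2fc = NULL,
                              baseline_mean = 100) {
  seed <- assert_count(seed, "seed", min = 0L)
  genome_length <- assert_count(genome_length, "genome_length", min = 1L)
  n_strains <- assert_count(n_strains, "n_strains", min = 1L)
  n_contigs <- assert_count(n_contigs, "n_contigs", min = 1L)
  n_samples <- assert_count(n_samples, "n_samples", min = 1L)
  reads_per_sample <- assert_count(reads_per_sample, "reads_per_sample", min = 0L)
  read_length <- assert_count(read_length, "read_length", min = 1L)
  n_core_families <- assert_count(n_core_families, "n_core_families", min = 1L)
  n_accessory_families <- assert_count(n_accessory_families, "n_accessory_families", min = 0L)
  n_genes_expr <- assert_count(n_genes_expr, "n_genes_expr", min = 1L)
  n_samples_per_group <- assert_count(n_samples_per_group, "n_samples_per_group", min = 2L)

  strain_ids <- sprintf("strain_%02d", seq_len(n_strains))
  if (is.null(substitution_rates)) {
    substitution_rates <- if (n_strains == 1L) 0 else
      seq(0.001, 0.012, length.out = n_strains)
  }
  if (length(substitution_rates) == 1L) {
    substitution_rates <- rep(substitution_rates, n_strains)
  }
  if (length(substitution_rates) != n_strains) {
    abort("`substitution_rates` must have one entry per strain.",
          class = "protoselect_config_error")
  }
  assert_fraction(substitution_rates, "substitution_rates")
  if (is.null(names(substitution_rates))) names(substitution_rates) <- strain_ids
  assert_fraction(indel_rate, "indel_rate")
  assert_fraction(read_error_rate, "read_error_rate")
  assert_fraction(protein_divergence, "protein_divergence")
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    abort("`nb_dispersion` must be non-negative.",
          class = "protoselect_config_error")
  }
  if (!is.numeric(baseline_mean) || baseline_mean <= 0) {
    abort("`baseline_mean` must be positive.", class = "protoselect_config_error")
  }

  if (!is.null(strain_mixtures)) {
    for (mix in strain_mixtures) {
      if (is.null(names(mix)) || !all(names(mix) %in% names(substitution_rates))) {
        abort("strain_mixtures must be named by simulated strain ids.",
              class = "protoselect_config_error")
      }
      if (abs(sum(mix) - 1) > 1e-9) {
        abort("each strain mixture must sum to 1 (tolerance 1e-9).",
              class = "protoselect_config_error")
      }
    }
  }

  if (is.null(planted_unique)) {
    planted_unique <- setNames(5L, strain_ids[1L])
  }
  if (length(planted_unique) &&
      (is.null(names(planted_unique)) ||
       !all(names(planted_unique) %in% strain_ids))) {
    abort("`planted_unique` must be named by simulated strain ids.",
          class = "protoselect_config_error")
  }

  gene_ids <- sprintf("gene_%04d", seq_len(n_genes_expr))
  if (is.null(planted_log2fc)) {
    n_up <- min(50L, n_genes_expr)
    n_dn <- min(50L, max(0L, n_genes_expr - n_up))
    planted_log2fc <- setNames(
      c(rep(2, n_up), rep(-2, n_dn)),
      gene_ids[seq_len(n_up + n_dn)]
    )
  }
  if (length(planted_log2fc) &&
      (is.null(names(planted_log2fc)) ||
       !all(names(planted_log2fc) %in% gene_ids))) {
    abort("`planted_log2fc` must be named by gene ids (gene_0001, ...).",
          class = "protoselect_config_error")
  }

  coverage <- rep_len(coverage, n_strains)
  source <- rep_len(source, n_strains)
  if (!all(source %in% c("public", "biobank"))) {
    abort('`source` labels must be "public" or "biobank".',
          class = "protoselect_config_error")
  }

  structure(
    list(
      seed = seed,
      genome_length = genome_length,
      n_strains = n_strains,
      strain_ids = strain_ids,
      substitution_rates = substitution_rates,
      indel_rate = indel_rate,
      n_contigs = n_contigs,
      coverage = coverage,
      source = source,
      n_samples = n_samples,
      strain_mixtures = strain_mixtures,
      reads_per_sample = reads_per_sample,
      read_length = read_length,
      read_error_rate = read_error_rate,
      n_core_families = n_core_families,
      n_accessory_families = n_accessory_families,
      planted_unique = planted_unique,
      protein_length_range = as.integer(protein_length_range),
      protein_divergence = protein_divergence,
      n_genes_expr = n_genes_expr,
      gene_ids = gene_ids,
      n_samples_per_group = n_samples_per_group,
      nb_dispersion = nb_dispersion,
      planted_log2fc = planted_log2fc,
      baseline_mean = baseline_mean
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d strains x %d bp | %d metagenome samples\n",
              x$seed, x$n_strains, x$genome_length, x$n_samples))
  cat(sprintf("  proteome: %d core + %d accessory + %d unique families\n",
              x$n_core_families, x$n_accessory_families, sum(x$planted_unique)))
  cat(sprintf("  counts: %d genes, %d/group, dispersion %.3g, %d planted DE\n",
              x$n_genes_expr, x$n_samples_per_group, x$nb_dispersion,
              length(x$planted_log2fc)))
  invisible(x)
}

# run `code` under a seed derived from the master seed by a fixed per-stage
# offset, restoring the caller's RNG state afterwards
with_stage_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}
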