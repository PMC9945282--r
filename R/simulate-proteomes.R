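#' Simulate strain proteomes with planted gene-family structure
#'
#' Builds a pangenome with three family classes: core families present in
#' every strain, accessory families present in a random proper subset of
#' strains (at least two), and planted unique families present in exactly
#' one strain. Every family has an ancestral protein of random length drawn
#' from `protein_length_range`; each strain's copy is derived by independent
#' per-residue substitutions at `protein_divergence` (a substituted residue
#' becomes a uniformly chosen different amino acid). Family membership is
#' recorded as truth for clustering recovery checks.
#'
#' With exactly two strains there is no proper multi-strain subset, so
#' accessory families are placed in both strains.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with components
#'   * `proteomes`: tibble with columns `strain_id`, `protein_id`, `seq`;
#'   * `truth`: tibble with columns `family_id`, `strain_id`, `protein_id`,
#'     `class` (`"core"`, `"accessory"` or `"unique"`).
#' @export
simulate_proteomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_strains
  ids <- config$strain_ids

  with_stage_seed(config$seed, 303L, {
    lr <- config$protein_length_range
    fam_len <- function() sample(seq(lr[1], lr[2]), 1L)

    families <- list()
    add_family <- function(fid, strains, class) {
      anc <- sample(AA_ALPHABET20, fam_len(), replace = TRUE)
      families[[fid]] <<- list(id = fid, strains = strains, class = class,
                               ancestor = anc)
    }

    for (i in seq_len(config$n_core_families)) {
      add_family(sprintf("fam_core_%03d", i), ids, "core")
    }
    if (config$n_accessory_families > 0L) {
      for (i in seq_len(config$n_accessory_families)) {
        # subset size uniform on 2..(n-1); sample() misbehaves on scalars
        size <- if (n <= 2L) n else (2:(n - 1L))[sample.int(n - 2L, 1L)]
        add_family(sprintf("fam_acc_%03d", i), sort(sample(ids, size)),
                   "accessory")
      }
    }
    for (st in names(config$planted_unique)) {
      cnt <- config$planted_unique[[st]]
      if (cnt > 0L) {
        for (i in seq_len(cnt)) {
          add_family(sprintf("fam_uniq_%s_%02d", st, i), st, "unique")
        }
      }
    }

    # deterministic per-strain gene numbering in family declaration order
    counters <- setNames(integer(length(ids)), ids)
    rows <- list()
    for (fam in families) {
      for (st in fam$strains) {
        counters[[st]] <- counters[[st]] + 1L
        aa <- fam$ancestor
        if (config$protein_divergence > 0) {
          mut <- which(runif(length(aa)) < config$protein_divergence)
          if (length(mut)) {
            off <- sample.int(19L, length(mut), replace = TRUE)
            aa[mut] <- AA_ALPHABET20[
              (match(aa[mut], AA_ALPHABET20) - 1L + off) %% 20L + 1L]
          }
        }
        rows[[length(rows) + 1L]] <- tibble(
          family_id = fam$id,
          strain_id = st,
          protein_id = sprintf("%s_g%04d", st, counters[[st]]),
          class = fam$class,
          seq = paste(aa, collapse = "")
        )
      }
    }
    all_rows <- bind_rows(rows)

    list(
      proteomes = select(arrange(all_rows, .data$strain_id, .data$protein_id),
                         "strain_id", "protein_id", "seq"),
      truth = select(all_rows, "family_id", "strain_id", "protein_id", "class")
    )
  })
}
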