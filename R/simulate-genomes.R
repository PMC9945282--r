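#' Simulate a within-species genome set with known identity structure
#'
#' Draws a uniform-random ancestor genome and derives one genome per strain
#' by independent per-site substitutions at that strain's configured rate
#' (mutated bases are replaced by a uniformly chosen different base) and,
#' optionally, single-base indels at `indel_rate` (split evenly between
#' insertions and deletions). Under this neutral model the expected identity
#' between strains i and j is closed-form,
#' \deqn{E[\mathrm{id}_{ij}] = (1-p_i)(1-p_j) + p_i p_j / 3,}
#' and is recorded in the truth set so downstream ANI estimates can be
#' checked against it. Each genome is split into `config$n_contigs`
#' near-equal contigs and carries the coverage/source metadata from the
#' config.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with components
#'   * `genomes`: tibble with columns `genome_id`, `contigs` (list column of
#'     named character vectors), `coverage`, `source`;
#'   * `truth`: list with `ancestor`, `substitution_positions` (per strain),
#'     `expected_identity` (strain x strain matrix), and the per-strain
#'     substitution rates.
#' @export
#' @examples
#' sim <- simulate_genomes(simulation_config(seed = 7, n_strains = 3))
#' sim$truth$expected_identity
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 5000L) {
    abort("genome_length must be at least 5,000 bp.",
          class = "protoselect_config_error")
  }
  if (config$n_strains < 2L) {
    abort("at least 2 strains are required.", class = "protoselect_config_error")
  }
  p <- config$substitution_rates
  if (any(p > 0.3)) {
    abort("substitution rates above 0.3 are rejected: the closed-form identity model breaks down.",
          class = "protoselect_rate_error")
  }

  with_stage_seed(config$seed, 101L, {
    bases <- c("A", "C", "G", "T")
    L <- config$genome_length
    anc <- sample(bases, L, replace = TRUE)

    per_strain <- lapply(seq_len(config$n_strains), function(i) {
      g <- anc
      mut <- which(runif(L) < p[i])
      if (length(mut)) {
        off <- sample.int(3L, length(mut), replace = TRUE)
        g[mut] <- bases[(match(g[mut], bases) - 1L + off) %% 4L + 1L]
      }
      if (config$indel_rate > 0) {
        u <- runif(length(g))
        del <- u < config$indel_rate / 2
        ins <- u >= config$indel_rate / 2 & u < config$indel_rate
        if (any(ins)) {
          ins_at <- which(ins)
          pieces <- character(length(g))
          pieces[] <- g
          pieces[ins_at] <- paste0(g[ins_at],
                                   sample(bases, length(ins_at), replace = TRUE))
          g <- strsplit(paste(pieces[!del], collapse = ""), "")[[1]]
        } else if (any(del)) {
          g <- g[!del]
        }
      }
      list(seq = paste(g, collapse = ""), mutations = mut)
    })

    ids <- config$strain_ids
    contigs <- lapply(seq_along(per_strain), function(i) {
      split_contigs(per_strain[[i]]$seq, config$n_contigs, ids[i])
    })

    expected <- outer(p, p, function(pi, pj) (1 - pi) * (1 - pj) + pi * pj / 3)
    diag(expected) <- 1
    dimnames(expected) <- list(ids, ids)

    list(
      genomes = tibble(
        genome_id = ids,
        contigs = contigs,
        coverage = config$coverage,
        source = config$source
      ),
      truth = list(
        ancestor = paste(anc, collapse = ""),
        substitution_positions = setNames(lapply(per_strain, `[[`, "mutations"), ids),
        expected_identity = expected,
        substitution_rates = p
      )
    )
  })
}

# split one sequence into n near-equal contigs named <id>_c1, <id>_c2, ...
split_contigs <- function(seq, n, id) {
  L <- nchar(seq)
  n <- min(n, L)
  bounds <- floor(seq(0, L, length.out = n + 1))
  ctg <- substring(seq, bounds[-(n + 1)] + 1, bounds[-1])
  setNames(ctg, sprintf("%s_c%d", id, seq_len(n)))
}
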