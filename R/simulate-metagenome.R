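#' Simulate shotgun metagenome samples as read mixtures of known strains
#'
#' Emulates fecal shotgun sequencing over a strain database: each sample is
#' a mixture of simulated strains with known relative abundances; reads of
#' fixed length are drawn uniformly from the originating strain's contigs
#' (forward strand, so error-free reads are exact genome substrings) and
#' per-base substitution errors are applied at `read_error_rate`. Read
#' provenance is recorded so detection calls can be scored against truth.
#'
#' If `config$strain_mixtures` is `NULL`, each sample receives a random
#' two-strain mixture with Dirichlet(1, 1) weights.
#'
#' @param config A [simulation_config()].
#' @param genomes Genome tibble from [simulate_genomes()].
#'
#' @return A list with components
#'   * `samples`: tibble with columns `sample_id` and `reads` (list column
#'     of named character vectors, read id -> sequence);
#'   * `truth`: list with `mixtures` (per-sample named abundance vectors)
#'     and `composition` (tibble `sample_id`, `strain_id`, `n_reads`).
#' @export
simulate_metagenome <- function(config, genomes) {
  stopifnot(inherits(config, "sim_config"), is.data.frame(genomes))
  mixtures <- config$strain_mixtures
  if (!is.null(mixtures)) {
    bad <- setdiff(unlist(lapply(mixtures, names)), genomes$genome_id)
    if (length(bad)) {
      abort(paste0("strain_mixtures reference unknown strains: ",
                   paste(bad, collapse = ", ")),
            class = "protoselect_config_error")
    }
    for (mix in mixtures) {
      if (abs(sum(mix) - 1) > 1e-9) {
        abort("each strain mixture must sum to 1 (tolerance 1e-9).",
              class = "protoselect_config_error")
      }
    }
  }

  with_stage_seed(config$seed, 202L, {
    sample_ids <- sprintf("sample_%03d", seq_len(config$n_samples))
    if (is.null(mixtures)) {
      mixtures <- lapply(sample_ids, function(s) {
        picks <- sample(genomes$genome_id, min(2L, nrow(genomes)))
        w <- rgamma(length(picks), shape = 1)
        setNames(w / sum(w), picks)
      })
    }
    if (length(mixtures) != config$n_samples) {
      abort("need one strain mixture per sample.",
            class = "protoselect_config_error")
    }
    names(mixtures) <- sample_ids

    contig_seqs <- setNames(genomes$contigs, genomes$genome_id)

    out <- lapply(sample_ids, function(s) {
      mix <- mixtures[[s]]
      n <- config$reads_per_sample
      if (n == 0L) {
        return(list(reads = setNames(character(), character()),
                    composition = tibble(sample_id = character(),
                                         strain_id = character(),
                                         n_reads = integer())))
      }
      origin <- if (length(mix) == 1L) rep(names(mix), n) else
        sample(names(mix), n, replace = TRUE, prob = mix)
      reads <- character(n)
      for (st in unique(origin)) {
        idx <- which(origin == st)
        reads[idx] <- draw_reads(contig_seqs[[st]], length(idx),
                                 config$read_length)
      }
      reads <- apply_read_errors(reads, config$read_error_rate)
      comp <- as.data.frame(table(origin), stringsAsFactors = FALSE)
      list(
        reads = setNames(reads, sprintf("%s_r%06d", s, seq_len(n))),
        composition = tibble(sample_id = s, strain_id = comp$origin,
                             n_reads = as.integer(comp$Freq))
      )
    })

    list(
      samples = tibble(
        sample_id = sample_ids,
        reads = lapply(out, `[[`, "reads")
      ),
      truth = list(
        mixtures = mixtures,
        composition = bind_rows(lapply(out, `[[`, "composition"))
      )
    )
  })
}

# n reads of length rl drawn uniformly from the eligible positions of a
# contig set (contigs shorter than rl are skipped)
draw_reads <- function(contigs, n, rl) {
  eligible <- nchar(contigs) >= rl
  if (!any(eligible)) {
    abort("no contig is long enough for the configured read length.",
          class = "protoselect_config_error")
  }
  contigs <- contigs[eligible]
  npos <- nchar(contigs) - rl + 1L
  which_ctg <- if (length(contigs) == 1L) rep(1L, n) else
    sample(seq_along(contigs), n, replace = TRUE, prob = npos)
  starts <- floor(runif(n) * npos[which_ctg]) + 1L
  substring(contigs[which_ctg], starts, starts + rl - 1L)
}

# uniform substitution errors at per-base rate e
apply_read_errors <- function(reads, e) {
  if (e <= 0 || length(reads) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(reads), nchar(reads), e)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      alt <- setdiff(bases, cur)
      substr(reads[i], p, p) <- sample(alt, 1L)
    }
  }
  reads
}
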