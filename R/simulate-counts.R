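#' Simulate a two-condition RNA-seq count matrix with planted fold changes
#'
#' Draws gene counts from a negative binomial with mean `baseline_mean`
#' (variance mu + phi * mu^2, phi = `nb_dispersion`; phi = 0 gives Poisson
#' counts). Genes named in `planted_log2fc` have their treated-group mean
#' multiplied by `2^log2fc`; all other genes are null. Samples are labelled
#' `control_*` / `treated_*` with `n_samples_per_group` replicates each.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with components
#'   * `counts`: tibble, first column `gene_id`, one integer column per
#'     sample;
#'   * `groups`: tibble with columns `sample_id`, `group`;
#'   * `truth`: tibble with columns `gene_id`, `log2fc`, `is_de`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ns <- config$n_samples_per_group
  genes <- config$gene_ids
  phi <- config$nb_dispersion

  with_stage_seed(config$seed, 404L, {
    mu_ctrl <- rep(config$baseline_mean, length(genes))
    lfc <- setNames(rep(0, length(genes)), genes)
    lfc[names(config$planted_log2fc)] <- config$planted_log2fc
    mu_trt <- mu_ctrl * 2^lfc

    draw <- function(mu) {
      if (phi == 0) rpois(length(mu), mu) else
        rnbinom(length(mu), mu = mu, size = 1 / phi)
    }
    ctrl <- vapply(seq_len(ns), function(i) draw(mu_ctrl), numeric(length(genes)))
    trt <- vapply(seq_len(ns), function(i) draw(mu_trt), numeric(length(genes)))

    samples <- c(sprintf("control_%d", seq_len(ns)),
                 sprintf("treated_%d", seq_len(ns)))
    m <- cbind(ctrl, trt)
    colnames(m) <- samples
    counts <- bind_cols(tibble(gene_id = genes), as_tibble(m))

    list(
      counts = counts,
      groups = tibble(sample_id = samples,
                      group = rep(c("control", "treated"), each = ns)),
      truth = tibble(gene_id = genes, log2fc = unname(lfc), is_de = lfc != 0)
    )
  })
}
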