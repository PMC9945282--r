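#' Run the full prototype-strain selection pipeline
#'
#' Orchestrates the ecological + phylogenomic selection end to end:
#' genome QC -> ANI dereplication of the public genomes -> k-mer strain
#' tracking across the metagenome samples -> prevalence -> AxP ranking of
#' the dereplicated database -> biobank candidate ranking against the
#' top-AxP reference. All stages are deterministic given the inputs, so a
#' rerun reproduces the report byte for byte.
#'
#' @param genomes Genome tibble with `source` labels: `"public"` genomes
#'   form the reference database, `"biobank"` genomes are the local
#'   candidates.
#' @param samples Sample tibble (`sample_id`, `reads` list column).
#' @param proteomes Proteome tibble covering the database and biobank
#'   strains (needed for the PPOS half of the selector).
#' @param outdir Optional directory: per-stage TSVs plus `report.json` are
#'   written there.
#' @param min_coverage,max_contigs QC thresholds (see [qc_filter()]).
#' @param derep_threshold ANI dereplication threshold (default 0.99).
#' @param fragment_length,k_ani ANI parameters.
#' @param k_track,min_score,max_iterations Strain-tracking parameters.
#' @param ani_weight,bidirectional Selector parameters.
#'
#' @return Object of class `selection_report` with the per-stage tables,
#'   the top-AxP `reference_id` and the selected biobank `prototype_id`.
#'   `tidy()` returns the selector ranking, `glance()` a one-row summary.
#' @export
run_selection <- function(genomes, samples, proteomes, outdir = NULL,
                          min_coverage = 30, max_contigs = 100,
                          derep_threshold = 0.99,
                          fragment_length = 1000L, k_ani = 16L,
                          k_track = 23L, min_score = 0.1,
                          max_iterations = 5L,
                          ani_weight = 0.5, bidirectional = FALSE) {
  qc <- qc_filter(genomes, min_coverage, max_contigs)
  pub <- qc_retained(qc[qc$source == "public", , drop = FALSE])
  if (nrow(pub) == 0L) {
    abort("qc stage: no public genome passed the quality filters.",
          class = "protoselect_stage_error")
  }

  ani <- ani_pairs(pub, fragment_length, k_ani)
  clusters <- dereplicate(pub, derep_threshold, ani = ani)
  reps <- pub[pub$genome_id %in%
                clusters$representative_id[clusters$is_representative], ,
              drop = FALSE]

  db <- build_kmer_db(reps, k_track)
  detections <- track_samples(db, samples, min_score, max_iterations)
  prev <- prevalence(detections, nrow(samples), strain_ids = reps$genome_id,
                     sample_ids = samples$sample_id)

  rep_ani <- ani[ani$query_id %in% reps$genome_id &
                   ani$ref_id %in% reps$genome_id, , drop = FALSE]
  axp <- axp_rank(rep_ani, prev)
  reference_id <- axp$strain_id[1]

  biobank <- qc_retained(qc[qc$source == "biobank", , drop = FALSE])
  if (nrow(biobank) == 0L) {
    abort("select stage: biobank is empty after QC.",
          class = "protoselect_empty_biobank")
  }
  all_qc <- qc_retained(qc)
  selector <- select_prototype(all_qc, proteomes, reference_id,
                               biobank$genome_id, ani_weight, bidirectional,
                               fragment_length, k_ani)

  report <- structure(
    list(
      qc = tibble(genome_id = qc$genome_id, coverage = qc$coverage,
                  n_contigs = vapply(qc$contigs, length, 1L),
                  source = qc$source, qc_pass = qc$qc_pass,
                  qc_reason = qc$qc_reason),
      ani = ani,
      clusters = clusters,
      detections = detections,
      prevalence = prev,
      axp = axp,
      selector = selector,
      reference_id = reference_id,
      prototype_id = selector$candidate_id[1],
      params = list(min_coverage = min_coverage, max_contigs = max_contigs,
                    derep_threshold = derep_threshold,
                    fragment_length = fragment_length, k_ani = k_ani,
                    k_track = k_track, min_score = min_score,
                    max_iterations = max_iterations,
                    ani_weight = ani_weight, bidirectional = bidirectional)
    ),
    class = "selection_report"
  )
  if (!is.null(outdir)) write_selection_report(report, outdir)
  report
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat(sprintf("  %d genomes QC'd, %d retained, %d database representatives\n",
              nrow(x$qc), sum(x$qc$qc_pass), sum(x$clusters$is_representative)))
  cat(sprintf("  top AxP reference: %s (AxP %.2f)\n", x$reference_id,
              x$axp$axp[1]))
  cat(sprintf("  selected biobank prototype: %s (combined %.2f)\n",
              x$prototype_id, x$selector$combined[1]))
  invisible(x)
}

#' @rdname run_selection
#' @param x,object A `selection_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.selection_report <- function(x, ...) x$selector

#' @rdname run_selection
#' @exportS3Method generics::glance
glance.selection_report <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$qc),
    n_qc_retained = sum(x$qc$qc_pass),
    n_representatives = sum(x$clusters$is_representative),
    n_samples = length(unique(x$detections$sample_id)),
    reference_id = x$reference_id,
    reference_axp = x$axp$axp[1],
    prototype_id = x$prototype_id,
    prototype_combined = x$selector$combined[1]
  )
}

#' AxP ranking plot for a selection run
#'
#' @param object A `selection_report`.
#' @param ... Unused.
#' @return A ggplot object showing mean ANI vs prevalence with AxP encoded
#'   as point size, the selected reference highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.selection_report <- function(object, ...) {
  axp <- mutate(object$axp, is_reference = .data$strain_id == object$reference_id)
  ggplot2::ggplot(axp, ggplot2::aes(x = .data$prevalence, y = .data$mean_ani,
                                    size = .data$axp,
                                    colour = .data$is_reference)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "prevalence across samples", y = "mean ANI to database",
                  size = "AxP") +
    ggplot2::theme_minimal()
}

write_selection_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$qc, file.path(outdir, "qc.tsv"))
  readr::write_tsv(report$ani, file.path(outdir, "ani.tsv"))
  readr::write_tsv(report$clusters, file.path(outdir, "clusters.tsv"))
  readr::write_tsv(report$detections, file.path(outdir, "detections.tsv"))
  readr::write_tsv(report$prevalence, file.path(outdir, "prevalence.tsv"))
  readr::write_tsv(report$axp, file.path(outdir, "axp.tsv"))
  readr::write_tsv(report$selector, file.path(outdir, "selector.tsv"))
  jsonlite::write_json(
    list(schema = "protoselect/selection-report/1",
         reference_id = report$reference_id,
         prototype_id = report$prototype_id,
         axp = report$axp,
         selector = report$selector,
         params = report$params),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(outdir)
}

#' Run the transcriptome (interactome) differential-expression stage
#'
#' CPM filter -> TMM normalization -> exact negative binomial test, with
#' the standard significance contract (fold change >= 2 and FDR <= 0.05).
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param groups Sample-to-group tibble (two groups, >= 2 replicates each).
#' @param outdir Optional directory: results TSV, a volcano-plot table
#'   (`log2fc`, `-log10 fdr`) and `dge_report.json` are written there.
#' @inheritParams cpm_filter
#' @inheritParams test_de
#'
#' @return The `dge_fit` object (see [test_de()]).
#' @export
run_interactome <- function(counts, groups, outdir = NULL, min_cpm = 1,
                            min_samples = NULL, min_fc = 2, max_fdr = 0.05) {
  filtered <- cpm_filter(counts, groups, min_cpm, min_samples)
  factors <- tmm_factors(filtered)
  fit <- test_de(filtered, groups, factors, min_fc, max_fdr)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(tidy(fit), file.path(outdir, "dge_results.tsv"))
    readr::write_tsv(
      mutate(select(tidy(fit), "gene_id", "log2fc", "fdr"),
             neg_log10_fdr = -log10(pmax(.data$fdr, 1e-300))),
      file.path(outdir, "volcano.tsv")
    )
    jsonlite::write_json(
      c(list(schema = "protoselect/dge-report/1"), as.list(glance(fit))),
      file.path(outdir, "dge_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  fit
}
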