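#' Basic assembly statistics per genome
#'
#' N50 is computed the standard way: sort contig lengths in decreasing
#' order; N50 is the length of the first contig at which the cumulative sum
#' reaches half the total assembly length.
#'
#' @param genomes Genome tibble (`genome_id`, `contigs`, ...).
#' @return Tibble with columns `genome_id`, `n_contigs`, `total_length`,
#'   `n50`.
#' @export
assembly_stats <- function(genomes) {
  stopifnot(is.data.frame(genomes), nrow(genomes) >= 1L)
  bad <- vapply(genomes$contigs, function(x) length(x) == 0L || any(nchar(x) == 0L),
                logical(1))
  if (any(bad)) {
    abort("empty genome (no contigs or zero-length contig).",
          class = "protoselect_empty_genome")
  }
  tibble(
    genome_id = genomes$genome_id,
    n_contigs = unname(vapply(genomes$contigs, length, 1L)),
    total_length = unname(vapply(genomes$contigs, function(x) sum(nchar(x)), 1.0)),
    n50 = unname(vapply(genomes$contigs, function(x) {
      len <- sort(nchar(x), decreasing = TRUE)
      len[which(cumsum(len) >= sum(len) / 2)[1]]
    }, 1.0))
  )
}

#' Quality-filter genome assemblies on coverage and contig count
#'
#' A genome is retained iff its sequencing coverage is strictly greater
#' than `min_coverage` (default 30-fold) and its contig count is strictly
#' less than `max_contigs` (default 100); boundary genomes (exactly 30x or
#' exactly 100 contigs) are rejected. Each rejected genome carries a reason
#' (`"low_coverage"` or `"too_many_contigs"`; low coverage wins when both
#' fail).
#'
#' @param genomes Genome tibble; the `coverage` column must be present and
#'   complete.
#' @param min_coverage Retain only coverage strictly above this value.
#' @param max_contigs Retain only contig counts strictly below this value.
#'
#' @return The input tibble plus logical `qc_pass` and character
#'   `qc_reason` (`NA` for retained genomes). Retained and rejected rows
#'   together are exactly the input.
#' @export
#' @examples
#' sim <- simulate_genomes(simulation_config(seed = 1, n_strains = 3))
#' qc <- qc_filter(sim$genomes)
#' table(qc$qc_pass)
qc_filter <- function(genomes, min_coverage = 30, max_contigs = 100) {
  stopifnot(is.data.frame(genomes))
  if (is.null(genomes$coverage) || anyNA(genomes$coverage)) {
    abort("coverage metadata is required for every genome; refusing to pass genomes silently.",
          class = "protoselect_missing_metadata")
  }
  if (anyDuplicated(genomes$genome_id)) {
    abort("genome_id values must be unique.", class = "protoselect_config_error")
  }
  n_contigs <- unname(vapply(genomes$contigs, length, 1L))
  low_cov <- unname(!(genomes$coverage > min_coverage))
  many_ctg <- !(n_contigs < max_contigs)
  genomes$qc_pass <- !low_cov & !many_ctg
  genomes$qc_reason <- dplyr::case_when(
    low_cov ~ "low_coverage",
    many_ctg ~ "too_many_contigs",
    TRUE ~ NA_character_
  )
  genomes
}

#' Keep only QC-passing genomes
#'
#' Convenience filter over [qc_filter()] output (runs [qc_filter()] first if
#' the QC columns are absent).
#'
#' @inheritParams qc_filter
#' @return Genome tibble restricted to retained genomes, QC columns dropped.
#' @export
qc_retained <- function(genomes, min_coverage = 30, max_contigs = 100) {
  if (!"qc_pass" %in% names(genomes)) {
    genomes <- qc_filter(genomes, min_coverage, max_contigs)
  }
  out <- genomes[genomes$qc_pass, , drop = FALSE]
  out$qc_pass <- NULL
  out$qc_reason <- NULL
  out
}
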