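#' Rank biobank candidates against a reference strain and pick a prototype
#'
#' For every biobank candidate the genomic closeness to the reference is
#' measured as ANI (percent) and the proteomic closeness as the mean PPOS
#' over best-hit protein pairs (candidate proteome as query); the two are
#' combined as `ani_weight * ANI% + (1 - ani_weight) * PPOS%` (default an
#' unweighted mean) and candidates are ranked by descending combined score
#' with ties broken by ANI then candidate id. A candidate with no
#' detectable protein homology to the reference is flagged (`NA` scores,
#' ranked last) instead of aborting the run; a candidate with no alignable
#' genome fragments is flagged the same way.
#'
#' @param genomes Genome tibble containing the reference and all
#'   candidates (all QC-passed).
#' @param proteomes Proteome tibble (`strain_id`, `protein_id`, `seq`)
#'   covering the reference and candidates.
#' @param reference_id Reference genome id (must not be a candidate).
#' @param candidate_ids Character vector of biobank candidate ids.
#' @param ani_weight Weight of the ANI percentage in the combined score.
#' @param bidirectional Passed to [proteome_mean_ppos()].
#' @inheritParams compute_ani
#'
#' @return Tibble with columns `candidate_id`, `ani_pct`, `mean_ppos`,
#'   `combined`, `flagged`, `rank` (ranks are a permutation of 1..n).
#' @export
select_prototype <- function(genomes, proteomes, reference_id, candidate_ids,
                             ani_weight = 0.5, bidirectional = FALSE,
                             fragment_length = 1000L, k = 16L) {
  if (length(candidate_ids) == 0L) {
    abort("biobank is empty: no candidate strains to rank.",
          class = "protoselect_empty_biobank")
  }
  if (reference_id %in% candidate_ids) {
    abort("the reference must not be among the candidates.",
          class = "protoselect_config_error")
  }
  ref_prot <- proteomes[proteomes$strain_id == reference_id, , drop = FALSE]

  rows <- lapply(sort(candidate_ids), function(cand) {
    ani_pct <- tryCatch(
      100 * compute_ani(genomes, cand, reference_id, fragment_length, k)$ani,
      protoselect_no_alignable_fragments = function(e) NA_real_
    )
    cand_prot <- proteomes[proteomes$strain_id == cand, , drop = FALSE]
    mp <- tryCatch(
      proteome_mean_ppos(cand_prot, ref_prot, proteome_a_id = cand,
                         proteome_b_id = reference_id,
                         bidirectional = bidirectional)$mean_ppos,
      protoselect_no_homology = function(e) NA_real_
    )
    tibble(candidate_id = cand, ani_pct = ani_pct, mean_ppos = mp,
           combined = ani_weight * ani_pct + (1 - ani_weight) * mp,
           flagged = is.na(ani_pct) || is.na(mp))
  })
  out <- bind_rows(rows)
  ord <- order(-ifelse(is.na(out$combined), -Inf, out$combined),
               -ifelse(is.na(out$ani_pct), -Inf, out$ani_pct),
               out$candidate_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}
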