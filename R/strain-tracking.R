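#' Build a canonical k-mer database over dereplicated reference genomes
#'
#' Indexes every canonical k-mer of every contig (windows containing `N` or
#' other ambiguity codes are skipped) per strain. Detection scores are
#' containment fractions against these per-strain sets.
#'
#' @param genomes Genome tibble (typically dereplication representatives).
#' @param k Odd k-mer length (default 23).
#' @return Object of class `kmer_db`: list with `k`, `strain_ids` and
#'   `kmers` (named list of distinct canonical k-mer vectors).
#' @export
build_kmer_db <- function(genomes, k = 23L) {
  k <- assert_count(k, "k")
  if (k %% 2L == 0L) {
    abort("k must be odd so no k-mer equals its own reverse complement.",
          class = "protoselect_config_error")
  }
  min_ctg <- min(unlist(lapply(genomes$contigs, nchar)))
  if (k > min_ctg) {
    abort("k exceeds the shortest contig length.",
          class = "protoselect_config_error")
  }
  kmers <- lapply(genomes$contigs, function(ctgs) unique(canonical_kmers(ctgs, k)))
  empty <- vapply(kmers, length, 1L) == 0L
  if (any(empty)) {
    abort(sprintf("no indexable k-mers (all-ambiguity contigs?) for: %s",
                  paste(genomes$genome_id[empty], collapse = ", ")),
          class = "protoselect_empty_kmer_set")
  }
  structure(
    list(k = k, strain_ids = genomes$genome_id,
         kmers = setNames(kmers, genomes$genome_id)),
    class = "kmer_db"
  )
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("<kmer_db> k=%d, %d strains, %s distinct k-mers/strain (median)\n",
              x$k, length(x$strain_ids),
              format(stats::median(vapply(x$kmers, length, 1L)), big.mark = ",")))
  invisible(x)
}

#' Detect reference strains present in one metagenomic read set
#'
#' Iterative winner-takes-all containment scoring in the spirit of
#' StrainGST: the distinct canonical k-mers of all reads form the sample
#' set S; each strain is scored as |strain k-mers in S| / |strain k-mers|;
#' the top-scoring strain (ties broken by lexicographically smaller strain
#' id) is emitted if its score reaches `min_score`, its k-mers are removed
#' from S, and the procedure repeats until no strain passes or
#' `max_iterations` winners have been emitted.
#'
#' @param db A [build_kmer_db()] database.
#' @param reads Character vector of read sequences (length >= `db$k` each;
#'   shorter reads contribute nothing). An empty vector yields an empty
#'   detection table, not an error.
#' @param min_score Minimum containment score to emit a detection.
#' @param max_iterations Maximum number of strains emitted per sample.
#' @param sample_id Label attached to the output rows.
#'
#' @return Tibble with columns `sample_id`, `strain_id`, `score`,
#'   `iteration`.
#' @export
detect_strains <- function(db, reads, min_score = 0.1, max_iterations = 5L,
                           sample_id = "sample") {
  stopifnot(inherits(db, "kmer_db"))
  out <- tibble(sample_id = character(), strain_id = character(),
                score = double(), iteration = integer())
  if (length(reads) == 0L) return(out)
  s_set <- unique(canonical_kmers(reads, db$k))
  if (length(s_set) == 0L) return(out)

  remaining <- db$strain_ids
  for (it in seq_len(max_iterations)) {
    if (!length(remaining) || !length(s_set)) break
    scores <- vapply(remaining, function(id) {
      km <- db$kmers[[id]]
      sum(km %in% s_set) / length(km)
    }, 1.0)
    top <- max(scores)
    if (top < min_score) break
    winner <- sort(remaining[scores == top])[1L]
    out <- bind_rows(out, tibble(sample_id = sample_id, strain_id = winner,
                                 score = unname(top), iteration = it))
    s_set <- setdiff(s_set, db$kmers[[winner]])
    remaining <- setdiff(remaining, winner)
  }
  out
}

#' Detect strains across a table of samples
#'
#' Maps [detect_strains()] over a sample tibble (as produced by
#' [simulate_metagenome()] or [read_samples()]).
#'
#' @param db A [build_kmer_db()] database.
#' @param samples Tibble with columns `sample_id` and `reads` (list column).
#' @inheritParams detect_strains
#' @return Detection tibble over all samples.
#' @export
track_samples <- function(db, samples, min_score = 0.1, max_iterations = 5L) {
  bind_rows(lapply(seq_len(nrow(samples)), function(i) {
    detect_strains(db, samples$reads[[i]], min_score, max_iterations,
                   sample_id = samples$sample_id[i])
  }))
}

#' Per-strain prevalence across metagenome samples
#'
#' Prevalence is the fraction of samples in which a strain was detected at
#' least once (detection is binary per sample; repeated detections in one
#' sample count once).
#'
#' @param detections Detection tibble from [track_samples()].
#' @param n_samples Total number of samples screened.
#' @param strain_ids Optional strain universe; strains never detected get
#'   prevalence 0. Defaults to the strains appearing in `detections`.
#' @param sample_ids Optional sample universe used to validate detections.
#'
#' @return Tibble with columns `strain_id`, `n_detected`, `prevalence`.
#' @export
prevalence <- function(detections, n_samples, strain_ids = NULL,
                       sample_ids = NULL) {
  n_samples <- assert_count(n_samples, "n_samples")
  if (!is.null(sample_ids)) {
    bad <- setdiff(detections$sample_id, sample_ids)
    if (length(bad)) {
      abort(paste0("detections reference unknown samples: ",
                   paste(bad, collapse = ", ")),
            class = "protoselect_unknown_id")
    }
  }
  if (is.null(strain_ids)) strain_ids <- sort(unique(detections$strain_id))
  hits <- distinct(detections, .data$strain_id, .data$sample_id)
  n_det <- table(factor(hits$strain_id, levels = strain_ids))
  tibble(
    strain_id = strain_ids,
    n_detected = as.integer(n_det),
    prevalence = as.integer(n_det) / n_samples
  )
}

#' Rank strains by the AxP index
#'
#' The AxP index of a strain is
#' \deqn{\mathrm{AxP} = \overline{\mathrm{ANI}} \times \mathrm{prevalence} \times 100,}
#' where mean ANI is the strain's average pairwise ANI to every *other*
#' genome in the database (a genome-centrality term; both factors are
#' fractions in `[0, 1]`, so AxP lies in `[0, 100]`). Strains are ranked by
#' descending AxP with ties broken by strain id.
#'
#' @param ani Pairwise ANI tibble from [ani_pairs()] covering every strain
#'   (unalignable pairs may be `NA`; they are excluded from the mean).
#' @param prevalence_table Tibble from [prevalence()].
#'
#' @return Tibble with columns `strain_id`, `mean_ani`, `prevalence`,
#'   `axp`, `rank`.
#' @export
#' @examples
#' ani <- tibble::tibble(query_id = "a", ref_id = "b", ani = 0.98)
#' prev <- tibble::tibble(strain_id = c("a", "b"), n_detected = c(1L, 0L),
#'                        prevalence = c(0.5, 0))
#' axp_rank(ani, prev)
axp_rank <- function(ani, prevalence_table) {
  strains <- prevalence_table$strain_id
  long <- bind_rows(
    tibble(strain_id = ani$query_id, other = ani$ref_id, ani = ani$ani),
    tibble(strain_id = ani$ref_id, other = ani$query_id, ani = ani$ani)
  )
  missing <- setdiff(strains, unique(long$strain_id))
  if (length(strains) > 1L && length(missing)) {
    abort(paste0("no ANI entries for strain(s): ",
                 paste(missing, collapse = ", ")),
          class = "protoselect_unknown_id")
  }
  mean_ani <- vapply(strains, function(s) {
    v <- long$ani[long$strain_id == s]
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 1.0)
  out <- tibble(
    strain_id = strains,
    mean_ani = unname(mean_ani),
    prevalence = prevalence_table$prevalence
  )
  out$axp <- out$mean_ani * out$prevalence * 100
  out <- arrange(out, desc(.data$axp), .data$strain_id)
  out$rank <- seq_len(nrow(out))
  out
}
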