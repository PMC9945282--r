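#' Fragment-based average nucleotide identity between two genomes
#'
#' ANIb-style estimator: the query genome is chopped into non-overlapping
#' `fragment_length`-bp fragments; each fragment is seeded onto the
#' reference by shared exact k-mers (both strands), the modal seed diagonal
#' picks a candidate region, and the fragment is globally aligned to that
#' region (match +1, mismatch -1, gap -2 per base, band 0.2 x
#' `fragment_length` around the diagonal). When every seed votes for a
#' single diagonal the band is degenerate and the alignment reduces to an
#' ungapped base-by-base comparison on that diagonal, which is computed
#' directly. A fragment is retained if it aligns over at least 70% of its
#' length with at least 30% identity; identity is matches / alignment
#' columns (gap columns included; `N` counts toward length, never as a
#' match). ANI in one direction is the mean identity of retained fragments;
#' the reported ANI is the mean of the two directions, so it is symmetric
#' in its arguments.
#'
#' @param genomes Genome tibble containing both ids.
#' @param a,b Genome ids of the pair.
#' @param fragment_length Fragment size in bp (default 1000).
#' @param k Seed k-mer length (default 16).
#'
#' @return One-row tibble: `query_id`, `ref_id`, `ani` (fraction in
#'   `[0, 1]`), `n_fragments_used`, `n_fragments_total` (both summed over
#'   the two directions).
#' @export
#' @examples
#' sim <- simulate_genomes(simulation_config(seed = 3, n_strains = 2,
#'                                           substitution_rates = c(0, 0.01)))
#' compute_ani(sim$genomes, "strain_01", "strain_02")
compute_ani <- function(genomes, a, b, fragment_length = 1000L, k = 16L) {
  ga <- genome_contigs(genomes, a)
  gb <- genome_contigs(genomes, b)
  for (g in list(ga, gb)) {
    if (sum(nchar(g)) < 2L * fragment_length) {
      abort("both genomes must be at least 2 x fragment_length long.",
            class = "protoselect_config_error")
    }
  }
  d1 <- ani_directed(ga, gb, fragment_length, k)
  d2 <- ani_directed(gb, ga, fragment_length, k)
  if (d1$used == 0L || d2$used == 0L) {
    abort(sprintf("no alignable fragments between %s and %s.", a, b),
          class = "protoselect_no_alignable_fragments")
  }
  tibble(
    query_id = a, ref_id = b,
    ani = mean(c(d1$ani, d2$ani)),
    n_fragments_used = d1$used + d2$used,
    n_fragments_total = d1$total + d2$total
  )
}

#' Pairwise ANI over a genome set
#'
#' Applies [compute_ani()] to every unordered genome pair. Pairs with no
#' alignable fragments are reported with `ani = NA`.
#'
#' @inheritParams compute_ani
#' @return Long tibble, one row per unordered pair.
#' @export
ani_pairs <- function(genomes, fragment_length = 1000L, k = 16L) {
  ids <- genomes$genome_id
  if (length(ids) < 2L) {
    return(tibble(query_id = character(), ref_id = character(), ani = double(),
                  n_fragments_used = integer(), n_fragments_total = integer()))
  }
  prs <- combn(ids, 2L)
  bind_rows(lapply(seq_len(ncol(prs)), function(j) {
    tryCatch(
      compute_ani(genomes, prs[1, j], prs[2, j], fragment_length, k),
      protoselect_no_alignable_fragments = function(e) {
        tibble(query_id = prs[1, j], ref_id = prs[2, j], ani = NA_real_,
               n_fragments_used = 0L, n_fragments_total = NA_integer_)
      }
    )
  }))
}

#' Dereplicate genomes by greedy centroid clustering at an ANI threshold
#'
#' Mirrors a dRep-style secondary clustering: genomes are ordered by a QC
#' score (coverage x (1 / n_contigs) x total_length, descending; ties broken
#' by genome id), the best unassigned genome seeds a cluster and every
#' unassigned genome with ANI >= `threshold` to the seed joins it; the seed
#' is the cluster representative. Pairs with no alignable fragments are
#' treated as below threshold.
#'
#' @param genomes Genome tibble (should already be QC-filtered).
#' @param threshold ANI threshold for joining a cluster (default 0.99, the
#'   redundancy cutoff used for within-species genome databases).
#' @param ani Optional precomputed pair table from [ani_pairs()]; computed
#'   on demand when `NULL`.
#' @inheritParams compute_ani
#'
#' @return Tibble with columns `genome_id`, `representative_id`,
#'   `is_representative`; clusters partition the input set.
#' @export
dereplicate <- function(genomes, threshold = 0.99, ani = NULL,
                        fragment_length = 1000L, k = 16L) {
  if (nrow(genomes) == 0L) {
    return(tibble(genome_id = character(), representative_id = character(),
                  is_representative = logical()))
  }
  stats <- assembly_stats(genomes)
  score <- genomes$coverage * (1 / stats$n_contigs) * stats$total_length
  ord <- order(-score, genomes$genome_id)
  ids <- genomes$genome_id[ord]

  lookup <- make_ani_lookup(genomes, ani, fragment_length, k)

  assigned <- setNames(rep(NA_character_, length(ids)), ids)
  for (seed in ids) {
    if (!is.na(assigned[[seed]])) next
    assigned[[seed]] <- seed
    for (cand in ids) {
      if (!is.na(assigned[[cand]])) next
      v <- lookup(seed, cand)
      if (!is.na(v) && v >= threshold) assigned[[cand]] <- seed
    }
  }
  tibble(
    genome_id = genomes$genome_id,
    representative_id = unname(assigned[genomes$genome_id]),
    is_representative = genomes$genome_id == unname(assigned[genomes$genome_id])
  )
}

# --- internals ---------------------------------------------------------------

genome_contigs <- function(genomes, id) {
  i <- match(id, genomes$genome_id)
  if (is.na(i)) {
    abort(sprintf("unknown genome id '%s'.", id),
          class = "protoselect_unknown_id")
  }
  genomes$contigs[[i]]
}

make_ani_lookup <- function(genomes, ani, fragment_length, k) {
  if (!is.null(ani)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    tab <- setNames(ani$ani, key(ani$query_id, ani$ref_id))
    function(a, b) {
      v <- tab[[key(a, b)]]
      if (is.null(v)) NA_real_ else v
    }
  } else {
    cache <- new.env(parent = emptyenv())
    function(a, b) {
      kk <- paste(pmin(a, b), pmax(a, b))
      if (!is.null(cache[[kk]])) return(cache[[kk]])
      v <- tryCatch(
        compute_ani(genomes, a, b, fragment_length, k)$ani,
        protoselect_no_alignable_fragments = function(e) NA_real_
      )
      cache[[kk]] <- v
      v
    }
  }
}

# one direction: fragments of `query` mapped onto `ref`
ani_directed <- function(query, ref, fragment_length, k,
                         min_cov = 0.70, min_ident = 0.30, seed_stride = 25L) {
  frags <- unlist(lapply(query, function(ctg) {
    L <- nchar(ctg)
    n <- L %/% fragment_length
    if (n == 0L) return(character())
    starts <- (seq_len(n) - 1L) * fragment_length + 1L
    substring(ctg, starts, starts + fragment_length - 1L)
  }), use.names = FALSE)
  total <- length(frags)
  if (total == 0L) return(list(ani = NA_real_, used = 0L, total = 0L))

  idx <- ref_seed_index(ref, k)
  band <- ceiling(0.2 * fragment_length)
  frags_rc <- revcomp(frags)

  idents <- rep(NA_real_, total)
  for (i in seq_len(total)) {
    idents[i] <- align_fragment(frags[i], frags_rc[i], ref, idx, k, band,
                                seed_stride, min_cov, min_ident)
  }
  used <- sum(!is.na(idents))
  list(ani = if (used) mean(idents, na.rm = TRUE) else NA_real_,
       used = used, total = total)
}

# forward-strand k-mer index of the reference: kmer -> encoded
# (contig, position); first occurrence wins
ref_seed_index <- function(ref, k) {
  BIG <- 2^26
  kms <- character(0)
  enc <- numeric(0)
  for (ci in seq_along(ref)) {
    kk <- forward_kmers(ref[[ci]], k)
    if (!length(kk)) next
    kms <- c(kms, kk)
    enc <- c(enc, (ci - 1) * BIG + seq_along(kk))
  }
  first <- !duplicated(kms)
  list(kmers = kms[first], enc = enc[first], BIG = BIG)
}

# returns identity of the retained alignment, or NA when the fragment does
# not seed/align acceptably
align_fragment <- function(frag, rcf, ref, idx, k, band, stride, min_cov,
                           min_ident) {
  fl <- nchar(frag)
  offs <- unique(c(seq(1L, fl - k + 1L, by = stride), fl - k + 1L))
  fwd <- substring(frag, offs, offs + k - 1L)
  rev <- substring(rcf, offs, offs + k - 1L)

  hf <- match(fwd, idx$kmers)
  hr <- match(rev, idx$kmers)
  use_rev <- sum(!is.na(hr)) > sum(!is.na(hf))
  hits <- if (use_rev) hr else hf
  seq_used <- if (use_rev) rcf else frag
  ok <- !is.na(hits)
  if (!any(ok)) return(NA_real_)

  enc <- idx$enc[hits[ok]]
  ctg <- (enc - 1) %/% idx$BIG + 1
  pos <- (enc - 1) %% idx$BIG + 1
  diag <- pos - offs[ok]
  key <- paste(ctg, diag)
  tab <- table(key)
  best <- names(tab)[which.max(tab)]
  votes <- max(tab)
  parts <- as.numeric(strsplit(best, " ")[[1]])
  bc <- parts[1]; bd <- parts[2]
  ctg_seq <- ref[[bc]]
  cl <- nchar(ctg_seq)

  if (votes == sum(ok)) {
    # unanimous diagonal: degenerate band, ungapped comparison
    s <- bd + 1
    e <- bd + fl
    qs <- 1L; qe <- fl
    if (s < 1) { qs <- qs + (1 - s); s <- 1 }
    if (e > cl) { qe <- qe - (e - cl); e <- cl }
    ncol_aln <- qe - qs + 1L
    if (ncol_aln < min_cov * fl) return(NA_real_)
    ident <- ungapped_identity(substr(seq_used, qs, qe), substr(ctg_seq, s, e))
    if (ident < min_ident) return(NA_real_)
    return(ident)
  }

  s <- max(1, bd + 1 - band)
  e <- min(cl, bd + fl + band)
  region <- substr(ctg_seq, s, e)
  if (nchar(region) < min_cov * fl) return(NA_real_)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_used), Biostrings::DNAString(region),
    type = "global-local", substitutionMatrix = dna_pm1_matrix(),
    gapOpening = 0, gapExtension = 2
  )
  ap <- as.character(Biostrings::alignedPattern(aln))
  as <- as.character(Biostrings::alignedSubject(aln))
  ncol_aln <- nchar(ap)
  q_res <- ncol_aln - lengths(regmatches(ap, gregexpr("-", ap, fixed = TRUE)))
  if (q_res < min_cov * fl) return(NA_real_)
  ident <- ungapped_identity(ap, as)
  if (ident < min_ident) return(NA_real_)
  ident
}

# identity over aligned strings of equal length: matches are equal A/C/G/T
# columns; every column (gap or N included) counts in the denominator
ungapped_identity <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  acgt <- charToRaw("ACGT")
  sum(ra == rb & ra %in% acgt) / length(ra)
}

# +1/-1 scoring over A,C,G,T,N with N never matching
dna_pm1_matrix <- function() {
  letters5 <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
}
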