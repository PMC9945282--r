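# BLOSUM62 is shipped with Biostrings; cached here after first use
.protein_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.protein_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .protein_env$BLOSUM62 <- e$BLOSUM62
  }
  .protein_env$BLOSUM62
}

# gapped Karlin-Altschul constants for BLOSUM62 (open 11 / extend 1);
# no edge-length correction is applied
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Smith-Waterman local alignment of two proteins
#'
#' Local alignment under BLOSUM62 with affine gaps (open 11, extend 1; a
#' gap of length L costs 11 + L). Identities are identical aligned residue
#' pairs; positives are aligned pairs with a positive BLOSUM62 score
#' (identities included); gap columns count toward the alignment length but
#' never toward identities or positives. The e-value is the ungapped-style
#' Karlin-Altschul estimate `K * m * n * exp(-lambda * S)` with the gapped
#' BLOSUM62 constants lambda = 0.267 and K = 0.041 (no length correction),
#' where m and n are the sequence lengths.
#'
#' @param query,subject Protein sequences (20-letter alphabet plus `X`).
#' @param query_id,subject_id Ids attached to the output row.
#'
#' @return One-row tibble: `query_id`, `subject_id`, `raw_score`,
#'   `identities`, `positives`, `alignment_length`, `query_cov`,
#'   `subject_cov`, `evalue`.
#' @export
#' @examples
#' local_align("MKTAYIAKQR", "MKTAYIAKQR")
local_align <- function(query, subject, query_id = "query",
                        subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject)) {
    abort("empty protein sequence.", class = "protoselect_empty_sequence")
  }
  align_pairs(tibble(query_id = query_id, subject_id = subject_id),
              setNames(query, query_id), setNames(subject, subject_id))
}

# batched Smith-Waterman over a candidate pair table; pairs sharing a
# subject are aligned in one vectorized pairwiseAlignment() call, which is
# what makes proteome-scale searches affordable in R
align_pairs <- function(pairs, seqs_q, seqs_s) {
  if (nrow(pairs) == 0L) return(empty_alignment_tbl())
  if (any(!nzchar(seqs_q)) || any(!nzchar(seqs_s))) {
    abort("empty protein sequence.", class = "protoselect_empty_sequence")
  }
  bl <- blosum62()
  chunks <- lapply(unique(pairs$subject_id), function(sid) {
    qids <- pairs$query_id[pairs$subject_id == sid]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs_q[qids]),
      Biostrings::AAString(seqs_s[[sid]]),
      type = "local", substitutionMatrix = bl,
      gapOpening = 11, gapExtension = 1
    )
    sc <- Biostrings::score(aln)
    m <- nchar(seqs_q[qids])
    n <- nchar(seqs_s[[sid]])
    identities <- Biostrings::nmatch(aln)
    # aligned-region widths: columns = query residues + gap columns in the
    # aligned query (deletion widths); positives = identities + mismatch
    # pairs scoring > 0 under BLOSUM62
    qw <- Biostrings::width(Biostrings::pattern(aln))
    sw <- Biostrings::width(Biostrings::subject(aln))
    del_w <- Biostrings::deletion(Biostrings::nindel(aln))[, "WidthSum"]
    mt <- Biostrings::mismatchTable(aln)
    pos_mm <- bl[cbind(as.character(mt$PatternSubstring),
                       as.character(mt$SubjectSubstring))] > 0
    positives <- identities +
      tabulate(mt$PatternId[pos_mm], nbins = length(aln))
    tibble(
      query_id = qids,
      subject_id = sid,
      raw_score = sc,
      identities = as.integer(identities),
      positives = as.integer(positives),
      alignment_length = as.integer(qw + del_w),
      query_cov = unname(qw / m),
      subject_cov = sw / n,
      evalue = unname(KA_K * m * n * exp(-KA_LAMBDA * sc))
    )
  })
  bind_rows(chunks)
}

#' Percentage of positive-scoring matches of an alignment
#'
#' PPOS = 100 x (identical + similar matches) / alignment length, where
#' similar means a positive substitution-matrix score; since identities
#' score positively under BLOSUM62, the numerator is simply the positives
#' count.
#'
#' @param alignment Alignment tibble from [local_align()] (any number of
#'   rows).
#' @return Numeric vector of PPOS percentages, one per row.
#' @export
ppos <- function(alignment) {
  if (any(alignment$alignment_length == 0)) {
    abort("zero-length alignment.", class = "protoselect_empty_alignment")
  }
  100 * alignment$positives / alignment$alignment_length
}

#' Best protein hits from one proteome into another
#'
#' For each protein of proteome A, reports its highest-scoring local
#' alignment into proteome B with e-value at most `max_evalue`; score ties
#' are broken by the lexicographically smaller subject id. Proteins with no
#' qualifying hit are absent from the output. For large proteome pairs a
#' shared-3-mer prefilter restricts the candidate subjects (any alignment
#' able to clear the e-value cutoff contains a run of exact word matches at
#' desk scale); small pairs are aligned exhaustively.
#'
#' @param proteome_a,proteome_b Proteome tibbles (`protein_id`, `seq`).
#' @param max_evalue E-value cutoff (default 1e-5, the proteome-screening
#'   cutoff).
#' @param prefilter_threshold Align all pairs exhaustively when
#'   |A| x |B| is at most this many pairs.
#'
#' @return Alignment tibble (one row per query with a qualifying hit).
#' @export
best_hits <- function(proteome_a, proteome_b, max_evalue = 1e-5,
                      prefilter_threshold = 20000L) {
  stopifnot(nrow(proteome_a) >= 1L, nrow(proteome_b) >= 1L)
  n_pairs <- nrow(proteome_a) * nrow(proteome_b)
  cand <- if (n_pairs <= prefilter_threshold) {
    expand_pairs(proteome_a$protein_id, proteome_b$protein_id)
  } else {
    word_candidates(proteome_a, proteome_b, w = 3L)
  }
  if (nrow(cand) == 0L) return(empty_alignment_tbl())
  seq_a <- setNames(proteome_a$seq, proteome_a$protein_id)
  seq_b <- setNames(proteome_b$seq, proteome_b$protein_id)
  hits <- align_pairs(cand, seq_a, seq_b)
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_alignment_tbl())
  hits <- arrange(hits, .data$query_id, desc(.data$raw_score), .data$subject_id)
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Proteome-vs-proteome average PPOS over best-hit pairs
#'
#' The average PPOS of the best hits of proteome A into proteome B; with
#' `bidirectional = TRUE` the two directional averages are themselves
#' averaged.
#'
#' @inheritParams best_hits
#' @param proteome_a_id,proteome_b_id Labels for the output row.
#' @param bidirectional Average the A->B and B->A directional means.
#'
#' @return One-row tibble: `proteome_a`, `proteome_b`, `mean_ppos`
#'   (percent), `n_pairs`.
#' @export
proteome_mean_ppos <- function(proteome_a, proteome_b, max_evalue = 1e-5,
                               proteome_a_id = "A", proteome_b_id = "B",
                               bidirectional = FALSE) {
  ab <- best_hits(proteome_a, proteome_b, max_evalue)
  if (nrow(ab) == 0L) {
    abort(sprintf("no homologous best-hit pairs between %s and %s.",
                  proteome_a_id, proteome_b_id),
          class = "protoselect_no_homology")
  }
  mp <- mean(ppos(ab))
  n <- nrow(ab)
  if (bidirectional) {
    ba <- best_hits(proteome_b, proteome_a, max_evalue)
    if (nrow(ba)) {
      mp <- mean(c(mp, mean(ppos(ba))))
      n <- n + nrow(ba)
    }
  }
  tibble(proteome_a = proteome_a_id, proteome_b = proteome_b_id,
         mean_ppos = mp, n_pairs = n)
}

# --- internals ---------------------------------------------------------------

expand_pairs <- function(a, b) {
  tibble(query_id = rep(a, each = length(b)),
         subject_id = rep(b, times = length(a)))
}

# candidate query/subject pairs sharing at least one exact length-w word
word_candidates <- function(proteome_a, proteome_b, w = 3L) {
  words_of <- function(tbl) {
    out <- lapply(seq_len(nrow(tbl)), function(i) {
      unique(forward_kmers_aa(tbl$seq[i], w))
    })
    tibble(protein_id = rep(tbl$protein_id, lengths(out)),
           word = unlist(out, use.names = FALSE))
  }
  wa <- words_of(proteome_a)
  wb <- words_of(proteome_b)
  j <- dplyr::inner_join(wa, wb, by = "word",
                         relationship = "many-to-many",
                         suffix = c("_a", "_b"))
  distinct(tibble(query_id = j$protein_id_a, subject_id = j$protein_id_b))
}

forward_kmers_aa <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

empty_alignment_tbl <- function() {
  tibble(query_id = character(), subject_id = character(), raw_score = double(),
         identities = integer(), positives = integer(),
         alignment_length = integer(), query_cov = double(),
         subject_cov = double(), evalue = double())
}
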