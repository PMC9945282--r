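#' All-vs-all protein hit graph for pangenome clustering
#'
#' Aligns protein pairs across (and within) strains and keeps an undirected
#' edge for every pair whose local alignment satisfies all three
#' orthology-screen thresholds: e-value at most `max_evalue`, identity at
#' least `min_identity` over the alignment columns (gaps included in the
#' denominator), and an aligned region covering at least `min_coverage` of
#' *both* sequences. Because the Smith-Waterman score, identity and
#' coverage pair are symmetric in the two sequences, each unordered pair is
#' aligned once and the edge criteria are orientation-free. The edge weight
#' is `-log10(evalue)` capped at 200.
#'
#' @param proteomes Proteome tibble (`strain_id`, `protein_id`, `seq`);
#'   protein ids must be globally unique.
#' @param max_evalue E-value cutoff (default 1e-10, the pangenome screen).
#' @param min_identity Minimum identity fraction (default 0.5).
#' @param min_coverage Minimum aligned fraction of both sequences (default
#'   0.8).
#' @param prefilter_threshold Align all pairs exhaustively when the number
#'   of candidate pairs is at most this; larger inputs are prefiltered by
#'   shared 3-mer words.
#'
#' @return Object of class `hit_graph`: list with `genes` (tibble
#'   `gene_id`, `strain_id`) and `edges` (tibble `from`, `to`, `weight`).
#'   Isolated genes stay in `genes`.
#' @export
all_vs_all_hits <- function(proteomes, max_evalue = 1e-10, min_identity = 0.5,
                            min_coverage = 0.8, prefilter_threshold = 20000L) {
  if (length(unique(proteomes$strain_id)) < 2L) {
    abort("at least two proteomes are required.",
          class = "protoselect_config_error")
  }
  if (anyDuplicated(proteomes$protein_id)) {
    abort("protein ids must be globally unique across strains.",
          class = "protoselect_config_error")
  }
  genes <- tibble(gene_id = proteomes$protein_id,
                  strain_id = proteomes$strain_id)
  seqs <- setNames(proteomes$seq, proteomes$protein_id)

  n <- nrow(proteomes)
  if (n * (n - 1) / 2 <= prefilter_threshold) {
    prs <- combn(proteomes$protein_id, 2L)
    cand <- tibble(query_id = prs[1, ], subject_id = prs[2, ])
  } else {
    cand <- word_candidates(
      tibble(protein_id = proteomes$protein_id, seq = proteomes$seq),
      tibble(protein_id = proteomes$protein_id, seq = proteomes$seq)
    )
    cand <- cand[cand$query_id < cand$subject_id, , drop = FALSE]
  }

  aln <- align_pairs(cand, seqs, seqs)
  pass <- aln$evalue <= max_evalue &
    aln$identities / aln$alignment_length >= min_identity &
    aln$query_cov >= min_coverage & aln$subject_cov >= min_coverage
  edges <- tibble(
    from = aln$query_id[pass],
    to = aln$subject_id[pass],
    weight = pmin(-log10(pmax(aln$evalue[pass], 1e-300)), 200)
  )
  structure(list(genes = genes, edges = edges), class = "hit_graph")
}

#' @export
print.hit_graph <- function(x, ...) {
  cat(sprintf("<hit_graph> %d genes, %d edges\n", nrow(x$genes),
              nrow(x$edges)))
  invisible(x)
}

#' Markov clustering of the hit graph into gene families
#'
#' Standard MCL on the weighted undirected hit graph: the adjacency matrix
#' gains self-loops (weight = the node's maximum incident edge weight, 1
#' for isolated genes), columns are normalized to a stochastic matrix, and
#' expansion (matrix squaring) alternates with inflation (entrywise power
#' `inflation`, column renormalization) until the largest entry change
#' drops below `tol` or `max_iter` is reached; entries below 1e-8 are
#' pruned each iteration. Families are the connected components of the
#' converged matrix's nonzero pattern; singletons form their own family.
#' Family ids are assigned deterministically from the lexicographically
#' smallest member gene id.
#'
#' @param graph A [all_vs_all_hits()] result.
#' @param inflation Inflation exponent (default 1.5, common pangenome
#'   practice).
#' @param max_iter,tol Convergence controls.
#'
#' @return Tibble with columns `family_id`, `strain_id`, `gene_id`,
#'   partitioning the input genes; attribute `converged` is `FALSE` (with a
#'   warning) if `max_iter` was exhausted.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(graph, "hit_graph"))
  genes <- graph$genes
  n <- nrow(genes)
  ids <- genes$gene_id
  edges <- graph$edges

  if (n == 0L) {
    return(structure(tibble(family_id = character(), strain_id = character(),
                            gene_id = character()), converged = TRUE))
  }

  A <- Matrix::sparseMatrix(
    i = c(match(edges$from, ids), match(edges$to, ids)),
    j = c(match(edges$to, ids), match(edges$from, ids)),
    x = c(edges$weight, edges$weight),
    dims = c(n, n)
  )
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  A <- A + Matrix::Diagonal(n, loop)

  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    M %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- Matrix::drop0(M2 * (M2 >= 1e-8))
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("MCL did not converge within max_iter; returning current partition.",
         class = "protoselect_mcl_nonconvergence")
  }

  nz <- Matrix::which(M != 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[nz[, 1]], to = ids[nz[, 2]]),
    directed = FALSE, vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership[ids]

  fam_key <- vapply(split(ids, comp), min, "")
  out <- tibble(
    gene_id = ids,
    strain_id = genes$strain_id,
    family_id = paste0("fam|", unname(fam_key[as.character(comp)]))
  )
  out <- arrange(out, .data$family_id, .data$strain_id, .data$gene_id)
  structure(select(out, "family_id", "strain_id", "gene_id"),
            converged = converged)
}

#' Family-by-strain presence/absence (copy-count) matrix
#'
#' @param families Family tibble from [mcl_cluster()].
#' @param strain_ids Optional strain universe (columns); defaults to the
#'   strains present in `families`.
#' @return Tibble: one row per family (`family_id`), one integer column per
#'   strain with the member-gene count (0 = absent).
#' @export
presence_absence <- function(families, strain_ids = NULL) {
  if (is.null(strain_ids)) strain_ids <- sort(unique(families$strain_id))
  counts <- summarise(
    group_by(families, .data$family_id, .data$strain_id),
    n = dplyr::n(), .groups = "drop"
  )
  counts$strain_id <- factor(counts$strain_id, levels = strain_ids)
  wide <- tidyr::pivot_wider(counts, names_from = "strain_id",
                             values_from = "n", values_fill = 0L,
                             names_expand = TRUE)
  arrange(wide, .data$family_id)
}

#' Gene families unique to a focal strain
#'
#' Families with at least one member gene in the focal strain and none in
#' any other strain; a family with several focal copies is reported once.
#'
#' @param pa Presence/absence tibble from [presence_absence()].
#' @param focal Focal strain id (must be a column of `pa`).
#' @return Tibble with columns `family_id`, `n_copies` (focal copy count).
#' @export
unique_genes <- function(pa, focal) {
  strain_cols <- setdiff(names(pa), "family_id")
  if (!focal %in% strain_cols) {
    abort(sprintf("unknown focal strain '%s'.", focal),
          class = "protoselect_unknown_id")
  }
  others <- setdiff(strain_cols, focal)
  other_total <- if (length(others)) {
    Reduce(`+`, lapply(others, function(s) pa[[s]]))
  } else rep(0L, nrow(pa))
  keep <- pa[[focal]] >= 1L & other_total == 0L
  tibble(family_id = pa$family_id[keep], n_copies = pa[[focal]][keep])
}
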