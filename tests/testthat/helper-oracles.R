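# Independent oracles used to check the package's implementations.

blosum62_tbl <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# exhaustive affine-gap Smith-Waterman (no seeding, plain dynamic
# programming); gap of length L costs open + L * ext
sw_score_oracle <- function(a, b, bl = blosum62_tbl, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  M <- matrix(-Inf, m + 1, n + 1)
  X <- M
  Y <- M
  M[1, ] <- 0
  M[, 1] <- 0
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- bl[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# adjusted Rand index between two labellings of the same items
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- b * cc / nn
  (a - expected) / ((b + cc) / 2 - expected)
}

# canonical k-mer of one window, via Biostrings reverseComplement
canon_kmer_oracle <- function(km) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(km)))
  min(km, rc)
}

random_aa <- function(n) {
  paste(sample(rownames(blosum62_tbl)[1:20], n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genome tibble from raw contig vectors (QC metadata defaulted)
genome_tbl <- function(..., coverage = 100, source = "public") {
  ctgs <- list(...)
  tibble::tibble(
    genome_id = names(ctgs),
    contigs = lapply(ctgs, function(x) {
      if (is.null(names(x))) names(x) <- paste0("c", seq_along(x))
      x
    }),
    coverage = rep_len(coverage, length(ctgs)),
    source = rep_len(source, length(ctgs))
  )
}
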