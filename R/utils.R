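#' Canonical k-mers of a set of nucleotide sequences
#'
#' Enumerates every k-length window of every sequence, skips windows that
#' contain characters outside `A`, `C`, `G`, `T` (ambiguity codes such as `N`
#' never enter the index), and canonicalizes each window to the
#' lexicographically smaller of the forward k-mer and its reverse complement,
#' so both strands of a genome or read set index identically.
#'
#' @param seqs Character vector of nucleotide sequences (possibly of unequal
#'   lengths). Sequences shorter than `k` contribute nothing.
#' @param k Window length in bases.
#'
#' @return Character vector of canonical k-mers, one entry per retained
#'   window (duplicates kept; wrap in [unique()] for a k-mer set).
#' @export
canonical_kmers <- function(seqs, k) {
  if (!is.character(seqs)) seqs <- as.character(seqs)
  if (length(seqs) == 0L) return(character())
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
  k <- as.integer(k)
  lens <- nchar(seqs)
  keep <- lens >= k
  if (!any(keep)) return(character())
  seqs <- seqs[keep]
  lens <- lens[keep]
  rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  pieces <- lapply(unique(lens), function(L) {
    i <- lens == L
    kmers_fixed_length(seqs[i], rcs[i], L, k)
  })
  unlist(pieces, use.names = FALSE)
}

# k-mers for sequences sharing one length; iterates over the smaller of
# (offsets, sequences) so both a few long contigs and many short reads
# vectorize well
kmers_fixed_length <- function(fwd, rev, L, k) {
  nk <- L - k + 1L
  n <- length(fwd)
  if (n >= nk) {
    out <- lapply(seq_len(nk), function(i) {
      f <- substring(fwd, i, i + k - 1L)
      r <- substring(rev, L - i - k + 2L, L - i + 1L)
      cn <- pmin(f, r)
      cn[!grepl("[^ACGT]", f)]
    })
  } else {
    starts <- seq_len(nk)
    out <- lapply(seq_len(n), function(j) {
      f <- substring(fwd[j], starts, starts + k - 1L)
      r <- substring(rev[j], L - starts - k + 2L, L - starts + 1L)
      cn <- pmin(f, r)
      cn[!grepl("[^ACGT]", f)]
    })
  }
  unlist(out, use.names = FALSE)
}

# forward-strand k-mers of a single sequence (used by the ANI seeder, which
# handles strands explicitly)
forward_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# amino-acid alphabet used by the proteome simulator (20 standard residues)
AA_ALPHABET20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

assert_fraction <- function(x, name, allow_zero = TRUE) {
  lo_ok <- if (allow_zero) all(x >= 0) else all(x > 0)
  if (!is.numeric(x) || !lo_ok || !all(x <= 1)) {
    abort(sprintf("`%s` must be in [0, 1].", name),
          class = "protoselect_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "protoselect_config_error")
  }
  invisible(as.integer(x))
}

# geometric mean ignoring non-finite values
geomean <- function(x) exp(mean(log(x[is.finite(log(x))])))
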