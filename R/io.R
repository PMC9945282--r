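#' Read genome assemblies from FASTA plus a metadata table
#'
#' One FASTA file per strain; the metadata table supplies the sequencing
#' coverage and source label the QC stage requires.
#'
#' @param files Named character vector of FASTA paths; names are used as
#'   genome ids (unnamed: file base names without extension).
#' @param metadata Data frame with columns `genome_id`, `coverage` and
#'   optionally `source` (default `"public"`).
#'
#' @return Genome tibble (`genome_id`, `contigs`, `coverage`, `source`).
#' @export
read_genomes <- function(files, metadata) {
  if (is.null(names(files))) {
    names(files) <- sub("\\.(fa|fasta|fna)$", "", basename(files))
  }
  stopifnot(all(c("genome_id", "coverage") %in% names(metadata)))
  contigs <- lapply(files, function(f) {
    ss <- Biostrings::readDNAStringSet(f)
    setNames(as.character(ss), names(ss))
  })
  g <- tibble(genome_id = names(files), contigs = unname(contigs))
  g <- left_join(g, as_tibble(metadata), by = "genome_id")
  if (anyNA(g$coverage)) {
    abort("missing coverage metadata for some genomes.",
          class = "protoselect_missing_metadata")
  }
  if (is.null(g$source)) g$source <- "public"
  g$source[is.na(g$source)] <- "public"
  g
}

#' Write genome assemblies as one FASTA file per strain
#'
#' Also writes `metadata.tsv` (`genome_id`, `coverage`, `n_contigs`,
#' `source`) alongside the FASTA files.
#'
#' @param genomes Genome tibble.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written FASTA paths.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(genomes)), function(i) {
    p <- file.path(dir, paste0(genomes$genome_id[i], ".fasta"))
    ss <- Biostrings::DNAStringSet(genomes$contigs[[i]])
    Biostrings::writeXStringSet(ss, p, width = 80L)
    p
  }, "")
  readr::write_tsv(
    tibble(genome_id = genomes$genome_id,
           coverage = genomes$coverage,
           n_contigs = vapply(genomes$contigs, length, 1L),
           source = genomes$source),
    file.path(dir, "metadata.tsv")
  )
  invisible(paths)
}

#' Read per-strain proteomes from amino-acid FASTA
#'
#' @param files Named character vector of FASTA paths (names = strain ids;
#'   unnamed: base names).
#' @return Proteome tibble (`strain_id`, `protein_id`, `seq`).
#' @export
read_proteomes <- function(files) {
  if (is.null(names(files))) {
    names(files) <- sub("\\.(fa|faa|fasta)$", "", basename(files))
  }
  bind_rows(lapply(names(files), function(id) {
    ss <- Biostrings::readAAStringSet(files[[id]])
    tibble(strain_id = id,
           protein_id = sub("\\s.*$", "", names(ss)),
           seq = unname(as.character(ss)))
  }))
}

#' Write per-strain proteomes as amino-acid FASTA
#'
#' @param proteomes Proteome tibble (`strain_id`, `protein_id`, `seq`).
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_proteomes <- function(proteomes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(unique(proteomes$strain_id), function(id) {
    p <- file.path(dir, paste0(id, ".faa"))
    sub <- proteomes[proteomes$strain_id == id, ]
    Biostrings::writeXStringSet(
      setNames(Biostrings::AAStringSet(sub$seq), sub$protein_id), p, width = 80L)
    p
  }, "")
  invisible(paths)
}

#' Read metagenome samples from FASTQ files
#'
#' @param files Named character vector of FASTQ paths (names = sample ids;
#'   unnamed: base names).
#' @return Sample tibble (`sample_id`, `reads` list column).
#' @export
read_samples <- function(files) {
  if (is.null(names(files))) {
    names(files) <- sub("\\.(fq|fastq)$", "", basename(files))
  }
  tibble(
    sample_id = names(files),
    reads = lapply(unname(files), function(f) {
      ss <- Biostrings::readDNAStringSet(f, format = "fastq")
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    })
  )
}

#' Write metagenome samples as one FASTQ file per sample
#'
#' Base qualities are written as the fixed character `I` (Phred 40), the
#' convention this package uses for simulated reads.
#'
#' @param samples Sample tibble (`sample_id`, `reads` list column).
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(samples)), function(i) {
    p <- file.path(dir, paste0(samples$sample_id[i], ".fastq"))
    reads <- samples$reads[[i]]
    lines <- character(0)
    if (length(reads)) {
      lines <- as.vector(rbind(paste0("@", names(reads)),
                               unname(reads),
                               "+",
                               strrep("I", nchar(reads))))
    }
    writeLines(lines, p)
    p
  }, "")
  invisible(paths)
}

#' Read a gene count matrix and sample-to-group map from TSV
#'
#' @param counts_file TSV with a header row; first column `gene_id`, one
#'   column per sample.
#' @param groups_file TSV with columns `sample_id`, `group`.
#' @return List with `counts` and `groups` tibbles.
#' @export
read_counts <- function(counts_file, groups_file) {
  counts <- readr::read_tsv(counts_file, show_col_types = FALSE)
  groups <- readr::read_tsv(groups_file, show_col_types = FALSE)
  stopifnot(names(counts)[1] == "gene_id",
            all(c("sample_id", "group") %in% names(groups)))
  list(counts = counts, groups = groups)
}
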