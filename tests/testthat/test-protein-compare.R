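test_that("local alignment agrees with the exhaustive Smith-Waterman oracle", {
  set.seed(51)
  for (i in 1:25) {
    l1 <- sample(10:60, 1)
    l2 <- sample(10:60, 1)
    a <- random_aa(l1)
    b <- if (i %% 2 == 0) {
      # related pair: 20% substitutions of a
      s <- strsplit(a, "")[[1]]
      mut <- sample(l1, ceiling(l1 * 0.2))
      s[mut] <- vapply(mut, function(j) random_aa(1), "")
      paste(s, collapse = "")
    } else {
      random_aa(l2)
    }
    expect_equal(local_align(a, b)$raw_score, sw_score_oracle(a, b))
  }
})

test_that("identities, positives and PPOS follow the BLOSUM62 sign rule", {
  # identical sequence against itself
  p <- random_aa(50)
  self <- local_align(p, p)
  expect_equal(self$identities, 50L)
  expect_equal(self$positives, 50L)
  expect_equal(self$alignment_length, 50L)
  expect_equal(ppos(self), 100)

  # L<->M substitution scores positively (BLOSUM62(L,M) = 2 > 0):
  # 9 identities but 10 positives over 10 columns, so PPOS = 100
  a <- "MKTAYIAKQL"
  b <- "MKTAYIAKQM"
  expect_gt(blosum62_tbl["L", "M"], 0)
  aln <- local_align(a, b)
  expect_equal(aln$identities, 9L)
  expect_equal(aln$positives, 10L)
  expect_equal(aln$alignment_length, 10L)
  expect_equal(ppos(aln), 100)

  # PPOS arithmetic on a constructed row
  fake <- tibble::tibble(positives = 5L, alignment_length = 10L)
  expect_equal(ppos(fake), 50)
  expect_error(ppos(tibble::tibble(positives = 0L, alignment_length = 0L)),
               class = "protoselect_empty_alignment")
  expect_error(local_align("", "MKT"), class = "protoselect_empty_sequence")
})

test_that("best hits pick the top-scoring subject with lexicographic ties", {
  set.seed(52)
  prot <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"),
    seq = vapply(c(80, 100, 120), random_aa, "")
  )
  hits <- best_hits(prot, prot)
  expect_identical(hits$query_id, prot$protein_id)
  expect_identical(hits$subject_id, prot$protein_id)  # self hits win

  # duplicate identical subjects: smaller id chosen
  dup <- tibble::tibble(protein_id = c("z_copy", "a_copy"),
                        seq = rep(prot$seq[1], 2))
  h <- best_hits(prot[1, ], dup)
  expect_identical(h$subject_id, "a_copy")

  # unrelated random proteome: nothing clears the e-value cutoff
  rnd <- tibble::tibble(protein_id = "r1", seq = random_aa(90))
  expect_identical(nrow(best_hits(prot[1, ], rnd)), 0L)
})

test_that("mean PPOS is 100 on self and decreases with divergence", {
  w <- selection_world()
  prot <- w$proteomes
  p1 <- prot[prot$strain_id == "strain_01", ]
  self <- proteome_mean_ppos(p1, p1, proteome_a_id = "s1", proteome_b_id = "s1")
  expect_equal(self$mean_ppos, 100)
  expect_identical(self$n_pairs, nrow(p1))

  # divergence ladder: mean PPOS strictly decreases over 3 planted levels
  mk_div <- function(base, rate, seed) {
    set.seed(seed)
    tibble::tibble(
      protein_id = base$protein_id,
      seq = vapply(base$seq, function(s) {
        x <- strsplit(s, "")[[1]]
        mut <- which(runif(length(x)) < rate)
        x[mut] <- vapply(mut, function(j) random_aa(1), "")
        paste(x, collapse = "")
      }, "")
    )
  }
  levels <- vapply(c(0.02, 0.10, 0.25), function(r) {
    proteome_mean_ppos(mk_div(p1, r, 53), p1)$mean_ppos
  }, 1.0)
  expect_true(all(diff(levels) < 0))

  # single-protein proteomes reduce to a single alignment's PPOS
  one <- p1[1, ]
  expect_equal(proteome_mean_ppos(one, one)$mean_ppos,
               ppos(local_align(one$seq, one$seq)))

  # disjoint random proteomes: explicit no-homology error
  set.seed(54)
  ra <- tibble::tibble(protein_id = "a", seq = random_aa(100))
  rb <- tibble::tibble(protein_id = "b", seq = random_aa(100))
  expect_error(proteome_mean_ppos(ra, rb),
               class = "protoselect_no_homology")
})

test_that("PPOS is symmetric under query/subject swap", {
  set.seed(55)
  a <- random_aa(80)
  s <- strsplit(a, "")[[1]]
  mut <- sample(80, 12)
  s[mut] <- vapply(mut, function(j) random_aa(1), "")
  b <- paste(s, collapse = "")
  expect_equal(ppos(local_align(a, b)), ppos(local_align(b, a)))
})
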