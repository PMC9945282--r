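---
title: "Prototype strain selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype strain selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoselect)
```

`protoselect` selects a prototype strain for a bacterial species in two
moves: an *ecological* one (which genome is both central to the species'
genomic diversity and prevalent in the target habitat?) and a *practical*
one (which locally available strain is closest to that reference?). This
vignette records the models behind each stage, the parameters that matter,
what the synthetic test bed does and does not establish, and the design
decisions taken where the problem statement left the choice open.

## The AxP index

For each genome in a dereplicated species database,

$$\mathrm{AxP} = \overline{\mathrm{ANI}} \times \mathrm{prevalence} \times 100,$$

where $\overline{\mathrm{ANI}}$ is the genome's mean pairwise ANI to every
*other* database genome and prevalence is the fraction of metagenome
samples in which the strain is detected. Two conventions needed fixing:

* **Scale.** Both factors are kept as fractions in $[0,1]$, so the
  trailing $\times 100$ puts AxP on a 0–100 scale. Treating either factor
  as a percentage would make the index range 0–10,000 and the
  multiplication by 100 meaningless.
* **Self-exclusion.** $\overline{\mathrm{ANI}}$ averages over the *other*
  genomes. Including the self-comparison (ANI 1.0) would shift every score
  up by the same mean-preserving amount at fixed database size but mix
  database size into the centrality term.

Prevalence is binary per sample — a strain either is or is not detected —
because the detection stage reports presence, not abundance; repeated
detections within one sample cannot occur by construction and are guarded
against in `prevalence()` anyway.

## Fragment ANI

The ANI stage needs a desk-computable, fully specified estimator rather
than a wrapped external binary. `compute_ani()` implements an ANIb-style
procedure: 1,000-bp non-overlapping query fragments, seeded onto the
reference by shared 16-mers on both strands, aligned globally to the
candidate region (match +1, mismatch −1, gap −2 per base, band 0.2 ×
fragment length around the modal seed diagonal). Fragments aligning over
≥ 70% of their length with ≥ 30% identity are retained; ANI is the mean
retained-fragment identity, averaged over the two directions so the
reported value is exactly symmetric.

Numerical shortcut: when every seed votes for a single diagonal the band
degenerates and the optimal banded alignment is the gap-free comparison on
that diagonal, which is computed directly without dynamic programming.
This is what makes full pairwise ANI matrices affordable in pure R; with
indel-free simulations the shortcut covers essentially every fragment, and
disagreeing diagonals fall back to `Biostrings::pairwiseAlignment()`.

`N` bases count toward alignment length but never as matches. Identity is
matches / alignment columns, gaps included — the convention that keeps the
fragment estimate comparable to a global-alignment identity.

Dereplication mirrors a dRep-style greedy centroid rule: genomes ordered
by the QC score coverage × (1 / contigs) × length (ties by id), the best
unassigned genome seeds a cluster, and everything with ANI ≥ 0.99 to the
seed joins. Greedy centroid clustering was chosen over average-linkage
because it is deterministic, one-pass, and directly yields the
representative; the exact secondary-clustering linkage used by dRep is not
restated in the protocol this package follows.

## Strain tracking

Detection is a simplified StrainGST: canonical 23-mers (lexicographic
minimum of a window and its reverse complement; odd k so no window is its
own reverse complement) of the sample's reads form a set $S$; each
database strain is scored by containment, $|K_\mathrm{strain} \cap S| /
|K_\mathrm{strain}|$; the best-scoring strain above `min_score = 0.1` is
emitted, its k-mers are removed from $S$, and the loop repeats up to
`max_iterations = 5` times. Distinct k-mers (not multiplicities) make the
score robust to uneven coverage at small read counts. The defaults are
exposed because the original tool's internal scoring is not part of the
published protocol; winner-takes-all removal is what lets two strains
sharing > 90% of their k-mers be resolved, and the tests verify exact
composition recovery for two-strain mixtures down to 10% abundance.

## Protein layer: Smith–Waterman, PPOS, best hits

Protein closeness uses local alignment under BLOSUM62 with affine gap
costs 11 (open) + 1 per residue — BLAST's defaults. *Positives* are
aligned residue pairs with positive substitution score (identities
included), so

$$\mathrm{PPOS} = 100 \times \frac{\text{positives}}{\text{alignment length (with gaps)}}$$

equals the PPOS column a BLASTP user would see. E-values use the fixed
gapped Karlin–Altschul constants $\lambda = 0.267$, $K = 0.041$ with $m
\times n$ the product of sequence lengths and no finite-length
correction; absolute e-values only matter near the 1e-5 / 1e-10 cutoffs,
and the simulations place homologs far from the boundary. The engine is
`Biostrings::pairwiseAlignment()` batched per subject; the test suite
holds it to an exhaustive affine-gap dynamic-programming oracle
(score-identical on every random pair tried).

For the biobank screen the candidate proteome is the query and the
reference the subject; the protocol does not say whether the published
average was one- or two-directional, so one direction is the default and
`bidirectional = TRUE` averages both directional means.

## Pangenome

Orthology edges require e-value ≤ 1e-10, ≥ 50% identity over alignment
columns (gaps in the denominator, matching BLAST's `pident`), and an
aligned region covering ≥ 80% of *both* sequences — the dual-coverage rule
is what excludes perfect domain-level matches between a full-length
protein and a fragment. Score, identity and the coverage pair are
symmetric in the two sequences, so each unordered pair is aligned once and
the graph is orientation-free by construction (the published pipeline's
A→B/B→A reconciliation never arises).

Families come from Markov clustering on the weighted graph (weights
−log10 e-value capped at 200): self-loops at each node's maximum incident
weight, column-stochastic normalization, then alternating expansion
(matrix squaring) and inflation (entrywise power 1.5, renormalize),
pruning entries below 1e-8, until the largest entry change falls below
1e-6 or 100 iterations (non-convergence returns the current partition
with a warning). Inflation 1.5 is common pangenome practice; the upstream
pipeline states no value. Attractor components of the converged matrix
are the families; family ids derive deterministically from the smallest
member gene id. A focal strain's *unique genes* are families with at
least one focal member and none elsewhere — reported at family level, so
focal-internal duplicates count once.

## Differential expression

The count stage follows the standard small-replicate RNA-seq recipe with
every step specified rather than delegated: genes with CPM < 1 in more
than (all − smaller-group-size) samples are dropped (how many samples the
published filter required is unstated; at least the smaller group size is
the common edgeR idiom and is a flag); TMM factors follow the
Robinson–Oshlack definition exactly (upper-quartile-closest-to-mean
reference, 30%/5% double trim, precision-weighted mean of M, geometric
mean rescaled to 1) and reproduce `edgeR::calcNormFactors()` to 8 decimal
places in the cross-check test; testing uses the exact conditional
negative binomial test on group sums of pseudo-counts (counts rescaled to
the geometric-mean effective library size), with gene-wise method-of-
moments dispersions floored at 0 and shrunk halfway toward the matrix-wide
mean — a transparent stand-in for edgeR's empirical-Bayes machinery that
keeps the stage self-contained and desk-verifiable. Fold changes use a
prior count of 0.5 for stability at low counts. Significance is the
published contract verbatim: |fold change| ≥ 2 **and** BH-FDR ≤ 0.05.

Which exact-test variant (classic vs quasi-likelihood F) the published
analysis used is unstated; the classic exact test was chosen because its
null distribution is fully specified by the model above, making the
calibration tests (null uniformity, FDR control, power at planted
log2FC 2) meaningful statements about this package rather than about a
wrapped library.

## The synthetic world

The generators state a world once and the tests live in it:

* **Genomes** — a uniform-random ancestor (default 20 kb, far below real
  ~2.3 Mb bifidobacterial chromosomes but large enough for hundreds of
  fragments and k-mer statistics); per-strain i.i.d. substitutions at
  rates defaulting to an even ladder over 0.001–0.012, i.e. pairwise ANI
  ≈ 97.6–99.8%, the band observed within a bacterial subspecies. Expected
  identity is closed-form, $(1-p_i)(1-p_j) + p_ip_j/3$, and recorded as
  truth. Indels default to 0 so that bookkeeping stays exact; they can be
  switched on (single-base, insertion/deletion symmetric) at the price of
  an approximate truth value. Substitution rates above 0.3 are rejected —
  beyond that the independent-site identity model stops being a useful
  description.
* **Metagenomes** — reads drawn uniformly (forward strand, so error-free
  reads are exact substrings) from strains in proportion to per-sample
  abundances summing to 1 ± 1e-9; uniform substitution errors at 0.001
  per base (canonical k-mers make strand irrelevant to detection).
* **Proteomes** — core families in all strains, accessory families in
  random proper subsets (both strains when only two exist), planted
  unique families in exactly one strain; per-strain copies diverge at 2%
  per residue, enough to be realistic and far from the 50%-identity edge.
  Protein divergence is deliberately *not* coupled to the genomic
  substitution rates — the PPOS and ANI axes of the selector stay
  independently testable.
* **Counts** — negative binomial, constant baseline mean 100, dispersion
  0.1, 3 replicates per group (a typical in vitro triplicate; the
  calibration criteria use 5), 100 planted genes at log2FC ±2 among
  2,000.

Each generator derives its RNG stream from the master seed by a fixed
offset (+101, +202, +303, +404), restoring the caller's RNG state, so
stages are individually and jointly byte-reproducible.

What a green test does *not* establish: robustness to real error
profiles, GC bias, repeats, mobile elements, within-sample strain mixtures
of more than a few members, gene-wise mean/dispersion heterogeneity, or
library-composition effects beyond what TMM's model absorbs. The
generators are the stated world, not an emulator of any particular
sequencing platform.

One derived check was re-derived here: for a planted log2FC of 2 at
baseline 100, dispersion 0.1 and 5 replicates, the treated/control ratio
of sample means lies in [3, 5.3] with only ≈ 83% probability per gene
(Monte Carlo under the generative model), so the test asserts that the
*median* ratio over the 50 planted genes falls in that interval — the
same generative claim, made deterministic.

## Orchestration

`run_selection()` and `run_interactome()` chain the stages with explicit
R arguments (no hidden state); per-stage TSVs and a versioned JSON report
are written when `outdir` is given, and reruns on the same inputs are
byte-identical because nothing downstream of the generators uses
randomness. The command-line wrapper keeps configuration in JSON (with
unknown-key rejection) rather than YAML, matching the package's report
format and avoiding an extra parser dependency.

## Known limitations

* Fragment ANI assumes the two genomes are largely collinear at fragment
  scale; heavy rearrangement between fragment boundaries degrades the
  estimate (real ANI tools share this property).
* The e-value calibration is nominal, not empirical; it is used as a
  ranking/cutoff device, as in the original pipeline.
* The exact NB test with moment dispersions is slightly conservative at
  very small counts and does not shrink dispersions adaptively; the
  calibration tests bound the practical consequences at the stated world.
* Detection reports presence only; relative abundance estimation is out
  of scope.
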