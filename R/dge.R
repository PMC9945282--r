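# counts tibble (gene_id + sample columns) -> integer matrix
count_matrix <- function(counts) {
  stopifnot(names(counts)[1] == "gene_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (any(m < 0)) {
    abort("negative counts are not allowed.", class = "protoselect_config_error")
  }
  rownames(m) <- counts$gene_id
  m
}

check_groups <- function(m, groups) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  if (!setequal(colnames(m), groups$sample_id)) {
    abort("count matrix samples and group map disagree.",
          class = "protoselect_config_error")
  }
  g <- setNames(groups$group, groups$sample_id)[colnames(m)]
  lv <- unique(g)
  if (length(lv) != 2L) {
    abort("exactly two groups are required.", class = "protoselect_config_error")
  }
  # control first when the labels include it, else first-seen order
  if ("control" %in% lv) lv <- c("control", setdiff(lv, "control"))
  factor(g, levels = lv)
}

#' Counts per million
#'
#' @param counts Count tibble (`gene_id` + one column per sample).
#' @param lib_sizes Optional library sizes (default: column sums).
#' @return Tibble of the same shape with CPM values.
#' @export
cpm <- function(counts, lib_sizes = NULL) {
  m <- count_matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(m)
  if (any(lib_sizes <= 0)) {
    abort("library sizes must be positive.", class = "protoselect_config_error")
  }
  out <- t(t(m) / lib_sizes) * 1e6
  bind_cols(tibble(gene_id = counts$gene_id), as_tibble(out))
}

#' Filter genes with low counts on a CPM threshold
#'
#' Keeps genes whose CPM reaches `min_cpm` in at least `min_samples`
#' samples (default: the size of the smaller group), removing the
#' low-count genes (CPM < 1 under the defaults) before normalization and
#' testing.
#'
#' @param counts Count tibble.
#' @param groups Sample-to-group tibble (`sample_id`, `group`).
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Number of samples that must reach `min_cpm`
#'   (default: smaller group size).
#' @return The filtered count tibble.
#' @export
cpm_filter <- function(counts, groups, min_cpm = 1, min_samples = NULL) {
  m <- count_matrix(counts)
  g <- check_groups(m, groups)
  if (is.null(min_samples)) min_samples <- min(table(g))
  cc <- count_matrix(cpm(counts))
  keep <- rowSums(cc >= min_cpm) >= min_samples
  if (!any(keep)) {
    abort("all genes removed by the CPM filter.",
          class = "protoselect_all_filtered")
  }
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values normalization: against a reference sample
#' (the one whose upper-quartile CPM is closest to the mean upper
#' quartile), each sample's gene-wise log2 ratios M and average log2
#' abundances A are computed on genes positive in both; the M values are
#' doubly trimmed (`trim_m` of the M tails, `trim_a` of the A tails) and
#' combined by a precision-weighted mean (inverse asymptotic binomial
#' variance weights); the factor is 2 to that mean. Factors are rescaled so
#' their geometric mean is exactly 1.
#'
#' @param counts Filtered count tibble.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return Tibble with columns `sample_id`, `lib_size`, `factor`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- count_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) {
    abort("sample with zero library size.", class = "protoselect_config_error")
  }
  uq <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
  ref_i <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_one(m[, j], m[, ref_i], lib[j], lib[ref_i], trim_m, trim_a)
  }, 1.0)
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), lib_size = unname(lib), factor = unname(f))
}

# single-sample TMM factor against the reference column
tmm_one <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) return(1)
  obs <- obs[pos]
  ref <- ref[pos]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  if (max(abs(M)) < 1e-6) return(1)
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Exact negative binomial differential expression test
#'
#' Two-condition test on a filtered count matrix. Effective library sizes
#' are library size x TMM factor; fold changes are ratios of group mean CPM
#' with a prior count of 0.5; p-values come from the exact conditional
#' negative binomial test on group-summed pseudo-counts (counts rescaled to
#' a common effective library size), with gene-wise dispersion estimated by
#' the method of moments, floored at 0 and shrunk halfway toward the
#' matrix-wide mean dispersion. FDR is Benjamini-Hochberg. A gene is called
#' significant iff its fold change is at least 2 in either direction
#' (|log2FC| >= 1) *and* its FDR is at most `max_fdr`.
#'
#' @param counts Filtered count tibble.
#' @param groups Sample-to-group tibble; the `control` level (if named so)
#'   is the fold-change baseline.
#' @param factors Optional [tmm_factors()] output (computed when `NULL`).
#' @param min_fc Fold-change threshold for significance (default 2).
#' @param max_fdr FDR threshold for significance (default 0.05).
#'
#' @return Object of class `dge_fit`; `tidy()` gives the per-gene table
#'   (`gene_id`, `log2fc`, `pvalue`, `fdr`, `significant`), `glance()` the
#'   run summary, `autoplot()` a volcano plot.
#' @export
test_de <- function(counts, groups, factors = NULL, min_fc = 2,
                    max_fdr = 0.05) {
  m <- count_matrix(counts)
  g <- check_groups(m, groups)
  if (any(table(g) < 2L)) {
    abort("at least 2 samples per group are required.",
          class = "protoselect_config_error")
  }
  if (is.null(factors)) factors <- tmm_factors(counts)
  f <- setNames(factors$factor, factors$sample_id)[colnames(m)]
  eff_lib <- colSums(m) * f

  i1 <- which(g == levels(g)[1])  # baseline (control)
  i2 <- which(g == levels(g)[2])

  cpm_p <- t(t(m + 0.5) / eff_lib) * 1e6
  log2fc <- log2(rowMeans(cpm_p[, i2, drop = FALSE])) -
    log2(rowMeans(cpm_p[, i1, drop = FALSE]))

  # pseudo-counts at a common effective library size
  common <- exp(mean(log(eff_lib)))
  pseudo <- t(t(m) / eff_lib) * common

  phi_hat <- apply(pseudo, 1, function(x) {
    v <- (sum((x[i1] - mean(x[i1]))^2) + sum((x[i2] - mean(x[i2]))^2)) /
      (length(x) - 2)
    mu <- mean(x)
    if (mu <= 0) return(0)
    max(0, (v - mu) / mu^2)
  })
  phi <- (phi_hat + mean(phi_hat)) / 2

  s1 <- round(rowSums(pseudo[, i1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, i2, drop = FALSE]))
  n1 <- length(i1)
  n2 <- length(i2)
  pvalue <- vapply(seq_along(s1), function(i) {
    exact_nb_pvalue(s1[i], s2[i], n1, n2, phi[i])
  }, 1.0)

  fdr <- p.adjust(pvalue, method = "BH")
  tbl <- tibble(
    gene_id = rownames(m),
    log2fc = unname(log2fc),
    pvalue = pvalue,
    fdr = fdr,
    significant = abs(log2fc) >= log2(min_fc) & fdr <= max_fdr
  )
  structure(
    list(table = tbl, factors = factors,
         groups = tibble(sample_id = colnames(m), group = as.character(g)),
         baseline = levels(g)[1], contrast = levels(g)[2],
         params = list(min_fc = min_fc, max_fdr = max_fdr,
                       mean_dispersion = mean(phi))),
    class = "dge_fit"
  )
}

# exact conditional NB test: P-value of the observed split (s1, s2) of the
# total t = s1 + s2 between n1 and n2 samples sharing one mean, summing the
# probabilities of all splits at most as likely as the observed one
exact_nb_pvalue <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  if (t > 2e5) {
    # normal approximation for extreme totals (never reached at desk scale)
    p1 <- n1 / (n1 + n2)
    mu <- t * p1
    vr <- t * p1 * (1 - p1) * (1 + phi * t / (n1 + n2))
    z <- (s1 - mu) / sqrt(vr)
    return(2 * stats::pnorm(-abs(z)))
  }
  s <- 0:t
  if (phi > 0) {
    mu <- t / (n1 + n2)
    lp <- dnbinom(s, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(t - s, size = n2 / phi, mu = n2 * mu, log = TRUE)
    pr <- exp(lp - max(lp))
  } else {
    pr <- dbinom(s, t, n1 / (n1 + n2))
  }
  pr <- pr / sum(pr)
  obs <- pr[s1 + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]))
}

#' @export
print.dge_fit <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<dge_fit> %d genes tested (%s vs %s): %d significant (%d up, %d down)\n",
              s$n_genes, x$contrast, x$baseline, s$n_significant, s$n_up,
              s$n_down))
  invisible(x)
}

#' @rdname test_de
#' @param x A `dge_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dge_fit <- function(x, ...) x$table

#' @rdname test_de
#' @exportS3Method generics::glance
glance.dge_fit <- function(x, ...) {
  tbl <- x$table
  tibble(
    n_genes = nrow(tbl),
    n_significant = sum(tbl$significant),
    n_up = sum(tbl$significant & tbl$log2fc > 0),
    n_down = sum(tbl$significant & tbl$log2fc < 0),
    mean_dispersion = x$params$mean_dispersion
  )
}

#' Volcano plot of a differential expression fit
#'
#' @param object A `dge_fit` object.
#' @param ... Unused.
#' @return A ggplot object (log2 fold change vs -log10 FDR, significant
#'   genes highlighted).
#' @exportS3Method ggplot2::autoplot
autoplot.dge_fit <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(pmax(.data$fdr, 1e-300)),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(object$params$max_fdr),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change",
                  y = "-log10 FDR",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
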