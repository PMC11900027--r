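#' Welch two-sample t test
#'
#' Thin wrapper around the standard Welch test with Satterthwaite degrees
#' of freedom. When both samples have zero variance the statistic is
#' undefined unless the means differ (then the evidence is unbounded and a
#' zero p-value with infinite t is returned); equal constant samples return
#' missing values with a warning.
#'
#' @param x,y numeric vectors of length >= 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stopf("each sample needs at least two values")
  stderr2 <- var(x) / length(x) + var(y) / length(y)
  scale2 <- max(abs(c(x, y)), 1)^2
  if (stderr2 <= 1e-20 * scale2) { # both samples (numerically) constant
    if (abs(mean(x) - mean(y)) <= sqrt(1e-20 * scale2)) {
      warning("both samples constant and equal; Welch t undefined")
      return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  ht <- t.test(x, y)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param corrected apply the Yates continuity correction.
#' @return list with `chi2`, `df` (1) and `p`.
#' @export
chi2_2x2 <- function(table, corrected = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("table must be 2x2")
  if (any(table < 0)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("degenerate margins: every row and column sum must be positive")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  dev <- abs(table - expected)
  if (corrected) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, df = 1, p = pchisq(chi2, 1, lower.tail = FALSE))
}

#' Chi-square goodness of fit
#'
#' @param observed integer vector of cell counts.
#' @param expected_proportions probabilities per cell; must sum to one.
#' @return list with `chi2`, `df` (cells - 1) and `p`.
#' @export
chi2_gof <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions))
    stopf("observed and expected_proportions must align")
  if (any(observed < 0)) stopf("observations must be non-negative")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stopf("expected_proportions must sum to 1")
  if (any(expected_proportions <= 0))
    stopf("expected proportions must be positive")
  expected <- sum(observed) * expected_proportions
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Compare the proportions of large fold changes between two contrasts
#'
#' Among significant genes of each contrast, counts genes at or above the
#' |log2 fold change| threshold versus below, and tests the 2x2 table with
#' an (optionally Yates-corrected) chi-square. If a column margin is zero
#' (e.g. threshold 0 makes every gene "large" in both contrasts) the
#' proportions are identical by construction and `chi2 = 0, p = 1`.
#'
#' @param de_a,de_b DE result tables (from [nb_wald()]).
#' @param threshold_log2 |log2 fold change| cut-off; the default 2 is a
#'   fourfold change.
#' @param corrected Yates correction flag.
#' @return list with the 2x2 `counts` (rows: contrasts; columns: large,
#'   small), per-contrast proportions, `chi2`, `p`, `corrected`.
#' @export
proportion_large_changes <- function(de_a, de_b, threshold_log2 = 2,
                                     corrected = FALSE) {
  grab <- function(de) {
    sig <- de[!is.na(de$log2fc) & de$significant, ]
    if (!nrow(sig)) stopf("a contrast has no significant genes")
    c(large = sum(abs(sig$log2fc) >= threshold_log2),
      small = sum(abs(sig$log2fc) < threshold_log2))
  }
  counts <- rbind(a = grab(de_a), b = grab(de_b))
  prop <- counts[, "large"] / rowSums(counts)
  if (any(colSums(counts) == 0)) {
    res <- list(chi2 = 0, df = 1, p = 1)
  } else {
    res <- chi2_2x2(counts, corrected = corrected)
  }
  list(counts = counts, proportions = prop, threshold_log2 = threshold_log2,
       chi2 = res$chi2, p = res$p, corrected = corrected)
}

#' Amplitude contrast of the most extreme genes of two contrasts
#'
#' Selects, per contrast, the `k` significant genes with the largest
#' |log2 fold change| (or the smallest adjusted p-values), and compares the
#' two |log2 fold change| samples with a Welch t test; the ratio of their
#' means is the amplitude ratio.
#'
#' @param de_a,de_b DE result tables.
#' @param k genes per contrast (>= 2; the Welch degrees of freedom are
#'   undefined at k = 1).
#' @param rank_by `"lfc"` (default) or `"fdr"`.
#' @return list: `k`, per-contrast mean |log2fc|, `ratio` (a over b), `t`,
#'   `df`, `p`, and the selected gene identifiers.
#' @export
top_k_amplitude <- function(de_a, de_b, k = 20, rank_by = c("lfc", "fdr")) {
  rank_by <- match.arg(rank_by)
  if (k < 2) stopf("k must be at least 2 (Welch df undefined below that)")
  pick <- function(de) {
    sig <- de[!is.na(de$log2fc) & de$significant, ]
    if (nrow(sig) < k)
      stopf("only %d significant genes; choose k <= that", nrow(sig))
    ord <- if (rank_by == "lfc") order(-abs(sig$log2fc)) else order(sig$fdr)
    sig[ord[seq_len(k)], ]
  }
  a <- pick(de_a); b <- pick(de_b)
  wa <- abs(a$log2fc); wb <- abs(b$log2fc)
  ht <- welch_t(wa, wb)
  list(k = k, mean_abs_lfc_a = mean(wa), mean_abs_lfc_b = mean(wb),
       ratio = mean(wa) / mean(wb), t = ht$t, df = ht$df, p = ht$p,
       genes_a = a$gene_id, genes_b = b$gene_id)
}

#' Replicate-variance contrast between exposure schemes
#'
#' Per gene, the replicate standard deviation of variance-stabilized values
#' is computed within every acute and every chronic treatment group and
#' averaged on the log scale within scheme; the per-gene difference
#' `log(SD acute) - log(SD chronic)` eliminates gene-level effects by
#' construction. The interaction coefficient is the mean difference among
#' responding (DE) genes minus the mean among the rest, with a Welch t test
#' between the two groups of per-gene differences.
#'
#' @param vst_matrix genes x samples matrix of variance-stabilized values.
#' @param samples sample table aligned to columns (`treatment`, `scheme`).
#' @param de_flags logical vector per gene: is the gene differentially
#'   expressed (in the relevant scheme's contrasts)?
#' @return list: `coefficient` (log scale; `exp(coefficient)` is the SD
#'   ratio), `t`, `df`, `p`, per-gene differences, and the number of genes
#'   excluded for zero variance.
#' @export
variance_contrast <- function(vst_matrix, samples, de_flags) {
  if (length(de_flags) != nrow(vst_matrix))
    stopf("de_flags must have one entry per gene")
  scheme_logsd <- function(scheme) {
    trs <- unique(samples$treatment[samples$scheme == scheme])
    if (!length(trs)) stopf("no %s samples present", scheme)
    sds <- vapply(trs, function(tr) {
      idx <- which(samples$treatment == tr)
      if (length(idx) < 2)
        stopf("treatment %s has fewer than two replicates", tr)
      sqrt(row_vars(vst_matrix[, idx, drop = FALSE]))
    }, numeric(nrow(vst_matrix)))
    if (is.null(dim(sds))) sds <- matrix(sds, ncol = length(trs))
    rowMeans(log(sds))
  }
  d <- scheme_logsd("acute") - scheme_logsd("chronic")
  usable <- is.finite(d)
  n_excluded <- sum(!usable)
  if (n_excluded > 0)
    message(n_excluded, " genes with zero replicate variance excluded")
  d <- d[usable]
  flags <- de_flags[usable]
  if (!any(flags) || all(flags))
    stopf("need both DE and non-DE genes to contrast")
  ht <- welch_t(d[flags], d[!flags])
  list(coefficient = mean(d[flags]) - mean(d[!flags]),
       t = ht$t, df = ht$df, p = ht$p,
       log_sd_diff = d, de_flags = flags, n_excluded = n_excluded)
}

#' Hypergeometric (Fisher) gene-set enrichment
#'
#' One-sided enrichment p per annotation term via the hypergeometric upper
#' tail, BH adjustment across terms.
#'
#' @param de_set differentially expressed gene identifiers.
#' @param annotation named list term -> gene identifiers (subsets of the
#'   pool).
#' @param pool background gene identifiers.
#' @return data frame: term, term_size, overlap, odds_ratio, p, fdr.
#' @export
fisher_enrichment <- function(de_set, annotation, pool) {
  de_set <- unique(de_set)
  pool <- unique(pool)
  if (!all(de_set %in% pool)) stopf("de_set must be a subset of the pool")
  N <- length(pool)
  n_de <- length(de_set)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(unique(annotation[[term]]), pool)
    if (!length(genes)) {
      warning("term '", term, "' has no genes in the pool; skipped")
      return(NULL)
    }
    K <- length(genes)
    a <- length(intersect(genes, de_set))
    p <- phyper(a - 1, K, N - K, n_de, lower.tail = FALSE)
    b <- K - a
    cc <- n_de - a
    d <- N - K - cc
    or <- (a * d) / (b * cc) # Inf/NaN on empty margins, reported as-is
    data.frame(term = term, term_size = K, overlap = a, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no usable annotation terms")
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between empirical distribution functions with the
#' asymptotic two-sided p-value (ties permitted; the p-value is then
#' approximate).
#'
#' @param x,y numeric vectors.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ht <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}

#' Sample skewness
#'
#' Standardized third central moment (bias-uncorrected,
#' `m3 / m2^(3/2)` with population moments).
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return skewness value.
#' @export
skewness <- function(x) {
  if (length(x) < 3) stopf("need at least three values")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) stopf("zero variance; skewness undefined")
  mean((x - m)^3) / s2^1.5
}
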