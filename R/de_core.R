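#' Settings for the differential-expression engine
#'
#' @param min_count,min_samples a gene is retained when it has at least
#'   `min_count` counts in at least `min_samples` samples.
#' @param fdr_alpha significance threshold on BH-adjusted Wald p-values.
#' @param dispersion_floor,dispersion_cap bounds on the gene-wise
#'   method-of-moments dispersion estimate.
#' @param vst_pseudocount pseudocount of the shifted-log variance-stabilizing
#'   transform.
#' @param max_irls_iter,irls_tol iteration cap and convergence tolerance
#'   (max absolute coefficient change, natural-log scale) of the IRLS fit.
#' @return a validated list of class `de_settings`.
#' @export
de_settings <- function(min_count = 10,
                        min_samples = 8,
                        fdr_alpha = 0.05,
                        dispersion_floor = 0.01,
                        dispersion_cap = 10,
                        vst_pseudocount = 1,
                        max_irls_iter = 50,
                        irls_tol = 1e-6) {
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stopf("fdr_alpha must be in (0, 1)")
  if (dispersion_floor <= 0) stopf("dispersion_floor must be positive")
  if (dispersion_floor >= dispersion_cap)
    stopf("dispersion_floor must be below dispersion_cap")
  if (vst_pseudocount <= 0) stopf("vst_pseudocount must be positive")
  structure(list(min_count = min_count, min_samples = min_samples,
                 fdr_alpha = fdr_alpha,
                 dispersion_floor = dispersion_floor,
                 dispersion_cap = dispersion_cap,
                 vst_pseudocount = vst_pseudocount,
                 max_irls_iter = max_irls_iter, irls_tol = irls_tol),
            class = "de_settings")
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix")
  if (any(counts < 0, na.rm = TRUE)) stopf("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene and sample identifiers as dimnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stopf("gene and sample identifiers must be unique")
  invisible(counts)
}

#' Remove genes with insufficient counts
#'
#' Retains exactly the genes observed at `min_count` or more in at least
#' `min_samples` samples (both thresholds inclusive); gene order is
#' preserved.
#'
#' @param counts gene x sample count matrix with dimnames.
#' @param settings a [de_settings()].
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, settings = de_settings()) {
  check_count_matrix(counts)
  keep <- rowSums(counts >= settings$min_count) >= settings$min_samples
  if (!any(keep)) warning("no genes pass the count filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median (lower median on ties
#' across an even number of usable genes) over genes of the ratio between
#' the sample's count and the gene's geometric mean across samples, using
#' only genes with a strictly positive geometric mean. When no gene is
#' expressed in every sample, geometric means are computed over the positive
#' entries of each gene (documented fallback).
#'
#' @param counts gene x sample count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  logc <- log(counts)
  loggeo <- rowMeans(logc) # -Inf whenever a zero occurs
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    # fallback: geometric mean over positive entries only
    loggeo <- apply(counts, 1, function(r) {
      pos <- r > 0
      if (!any(pos)) -Inf else mean(log(r[pos]))
    })
    usable <- is.finite(loggeo)
    if (!any(usable))
      stopf(paste("no gene is usable for normalization (all-zero matrix);",
                  "supply more deeply sequenced samples"))
  }
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    ratios <- logc[usable, j] - loggeo[usable]
    ratios <- ratios[is.finite(ratios)]
    if (!length(ratios))
      stopf("sample %s shares no expressed gene with the rest of the data",
            colnames(counts)[j])
    exp(lower_median(ratios))
  }, numeric(1))
  setNames(sf, colnames(counts))
}

#' Gene-wise method-of-moments dispersion
#'
#' Within each replicated design cell (treatment group), the moments
#' estimator `(s^2 - m) / m^2` of the negative-binomial dispersion is
#' computed on normalized counts; estimates are pooled across cells with
#' degrees-of-freedom weights and clamped to `[floor, cap]`. Deterministic;
#' no shrinkage is applied.
#'
#' @param counts filtered gene x sample count matrix.
#' @param factors size factors from [size_factors()].
#' @param samples sample table with a `treatment` column aligned to the
#'   columns of `counts`.
#' @param settings a [de_settings()].
#' @return named numeric vector of dispersions per gene.
#' @export
estimate_dispersion <- function(counts, factors, samples,
                                settings = de_settings()) {
  check_count_matrix(counts)
  y <- sweep(counts, 2, factors, "/")
  num <- rep(0, nrow(y))
  den <- rep(0, nrow(y))
  for (tr in unique(samples$treatment)) {
    idx <- which(samples$treatment == tr)
    n <- length(idx)
    if (n < 2) next
    m <- rowMeans(y[, idx, drop = FALSE])
    v <- row_vars(y[, idx, drop = FALSE], m)
    ok <- m > 0
    num[ok] <- num[ok] + (n - 1) * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + (n - 1)
  }
  alpha <- ifelse(den > 0, num / pmax(den, 1), settings$dispersion_floor)
  alpha <- pmin(pmax(alpha, settings$dispersion_floor),
                settings$dispersion_cap)
  setNames(alpha, rownames(counts))
}

# One negative-binomial log-link GLM fitted by IRLS with fixed dispersion.
# Returns coefficients, standard errors and a convergence flag.
nb_irls_one <- function(y, X, offset, alpha, max_iter, tol) {
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- tryCatch(qr.solve(X, eta - offset), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  eta <- pmin(drop(X %*% beta) + offset, 30)
  mu <- exp(eta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    if (any(!is.finite(w)) || all(w <= 0)) break
    z <- (eta - offset) + (y - mu) / mu
    sw <- sqrt(w)
    fit <- tryCatch(.lm.fit(X * sw, z * sw), error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) break
    eta <- pmin(drop(X %*% beta_new) + offset, 30)
    mu <- exp(eta)
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    if (step < tol) { converged <- TRUE; break }
  }
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(w))
  covb <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  if (is.null(covb)) return(list(beta = beta, se = rep(NA_real_,
                                                       length(beta)),
                                 converged = FALSE))
  list(beta = beta, se = sqrt(pmax(diag(covb), 0)), converged = converged)
}

# Model matrix for intercept + treatment + colony, control and colony 1 as
# reference levels; errors on rank deficiency naming the aliased columns.
de_model_matrix <- function(samples) {
  trt <- factor(samples$treatment)
  if (!"control" %in% levels(trt))
    stopf("sample table must contain a 'control' treatment")
  trt <- stats::relevel(trt, ref = "control")
  dat <- data.frame(treatment = droplevels(trt))
  form <- ~treatment
  if (length(unique(samples$colony)) > 1) {
    dat$colony <- factor(samples$colony)
    form <- ~ treatment + colony
  }
  X <- model.matrix(form, dat)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }
  X
}

# Fit the NB GLM for every gene once; coefficient/SE matrices are on the
# natural-log scale. Internal workhorse shared by nb_wald()/nb_wald_all().
nb_fit_all <- function(counts, samples, settings,
                       factors = NULL, dispersions = NULL,
                       include_colony = TRUE) {
  check_count_matrix(counts)
  if (nrow(samples) != ncol(counts))
    stopf("sample table and count matrix disagree on sample number")
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, factors, samples, settings)
  smp <- samples
  if (!include_colony) smp$colony <- 1
  X <- de_model_matrix(smp)
  offset <- log(factors)
  ngene <- nrow(counts)
  beta <- matrix(NA_real_, ngene, ncol(X),
                 dimnames = list(rownames(counts), colnames(X)))
  se <- beta
  conv <- logical(ngene)
  for (g in seq_len(ngene)) {
    fit <- nb_irls_one(counts[g, ], X, offset, dispersions[g],
                       settings$max_irls_iter, settings$irls_tol)
    if (is.null(fit)) next
    beta[g, ] <- fit$beta
    se[g, ] <- fit$se
    conv[g] <- fit$converged
  }
  base_mean <- rowMeans(sweep(counts, 2, factors, "/"))
  list(beta = beta, se = se, converged = conv, base_mean = base_mean,
       factors = factors, dispersions = dispersions, design = X)
}

de_result_from_fit <- function(fit, contrast, settings) {
  col <- paste0("treatment", contrast)
  if (!col %in% colnames(fit$beta))
    stopf("contrast '%s' is not a treatment level of the fitted design",
          contrast)
  ln2 <- log(2)
  b <- fit$beta[, col]
  s <- fit$se[, col]
  ok <- fit$converged & is.finite(b) & is.finite(s) & s > 0
  z <- ifelse(ok, b / s, NA_real_)
  p <- 2 * pnorm(-abs(z))
  fdr <- bh_adjust(p)
  data.frame(gene_id = rownames(fit$beta),
             base_mean = unname(fit$base_mean),
             log2fc = unname(ifelse(ok, b / ln2, NA_real_)),
             se = unname(ifelse(ok, s / ln2, NA_real_)),
             wald_z = unname(z),
             pvalue = unname(p),
             fdr = unname(fdr),
             significant = unname(!is.na(fdr) & fdr < settings$fdr_alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Negative-binomial Wald test for one treatment contrast
#'
#' Fits, per gene, a negative-binomial log-link GLM of counts on treatment
#' and source colony (both dummy coded; control and colony 1 are reference
#' levels) with log size factors as offset and the gene's method-of-moments
#' dispersion held fixed, then tests the requested treatment coefficient
#' against zero with a two-sided Wald z test. P-values are BH-adjusted
#' across all retained genes; genes whose fit does not converge carry
#' missing statistics and are excluded from the adjustment.
#'
#' @param counts filtered gene x sample count matrix.
#' @param samples sample table (`treatment`, `colony`) aligned to columns.
#' @param settings a [de_settings()].
#' @param contrast treatment label to compare against control.
#' @param include_colony set to `FALSE` to drop the colony covariate (used
#'   by the colony-confounding diagnostic where colony is aliased with the
#'   comparison by construction).
#' @return data frame (one row per gene): gene_id, base_mean, log2fc, se,
#'   wald_z, pvalue, fdr, significant.
#' @export
nb_wald <- function(counts, samples, settings = de_settings(), contrast,
                    include_colony = TRUE) {
  fit <- nb_fit_all(counts, samples, settings,
                    include_colony = include_colony)
  de_result_from_fit(fit, contrast, settings)
}

#' Wald tests for every non-control treatment from a single model fit
#'
#' @inheritParams nb_wald
#' @return named list of per-contrast data frames (see [nb_wald()]).
#' @export
nb_wald_all <- function(counts, samples, settings = de_settings(),
                        include_colony = TRUE) {
  fit <- nb_fit_all(counts, samples, settings,
                    include_colony = include_colony)
  contrasts <- setdiff(unique(samples$treatment), "control")
  setNames(lapply(contrasts, de_result_from_fit, fit = fit,
                  settings = settings), contrasts)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing values propagate and are excluded from the number of tests.
#'
#' @param pvalues vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Shifted-log variance-stabilizing transform
#'
#' `log2(count / size_factor + pseudocount)`: a transparent stand-in for
#' more elaborate variance-stabilizing transforms, adequate for the
#' standard-deviation contrasts and PCA performed downstream.
#'
#' @param counts gene x sample count matrix.
#' @param factors size factors (positive).
#' @param settings a [de_settings()] (supplies the pseudocount).
#' @return numeric matrix of the same shape.
#' @export
vst_transform <- function(counts, factors, settings = de_settings()) {
  check_count_matrix(counts)
  if (any(factors <= 0)) stopf("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + settings$vst_pseudocount)
}

#' Principal component analysis of samples
#'
#' Genes are centred, samples decomposed by SVD. Variance fractions sum to
#' one (all zero for a degenerate constant matrix).
#'
#' @param transformed matrix (genes x samples) of variance-stabilized values.
#' @return list with `coordinates` (samples x components) and
#'   `var_explained` (fraction of variance per component).
#' @export
pca_samples <- function(transformed) {
  if (ncol(transformed) < 2) stopf("PCA needs at least two samples")
  pc <- prcomp(t(transformed), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  frac <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  list(coordinates = pc$x, var_explained = frac)
}
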