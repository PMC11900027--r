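#' Configuration for replicate-balance subsampling
#'
#' @param n_iterations number of resampling iterations.
#' @param target_n replicates drawn per arm.
#' @param unique_subsets forbid repeating a joint (control, treatment)
#'   subset.
#' @param seed RNG seed.
#' @return list of class `subsample_config`.
#' @export
subsample_config <- function(n_iterations = 50, target_n = 8,
                             unique_subsets = TRUE, seed = 1) {
  if (n_iterations < 1) stopf("n_iterations must be positive")
  if (target_n < 2) stopf("target_n must be at least 2")
  structure(list(n_iterations = as.integer(n_iterations),
                 target_n = as.integer(target_n),
                 unique_subsets = isTRUE(unique_subsets),
                 seed = as.integer(seed)),
            class = "subsample_config")
}

#' Configuration for colony-confounding resampling
#'
#' @param n_iterations resampling iterations per mode.
#' @param colonies_per_arm source colonies drawn per arm.
#' @param seed RNG seed.
#' @return list of class `confound_config`.
#' @export
confound_config <- function(n_iterations = 100, colonies_per_arm = 5,
                            seed = 1) {
  if (n_iterations < 1) stopf("n_iterations must be positive")
  if (colonies_per_arm < 1) stopf("colonies_per_arm must be positive")
  structure(list(n_iterations = as.integer(n_iterations),
                 colonies_per_arm = as.integer(colonies_per_arm),
                 seed = as.integer(seed)),
            class = "confound_config")
}

# Run the full DE pipeline (filter, size factors, dispersion, Wald) on a
# column subset and count FDR-significant genes for one contrast.
de_count_on_subset <- function(counts, samples, idx, contrast, settings,
                               include_colony = TRUE,
                               residual_dispersion = FALSE) {
  sub_counts <- counts[, idx, drop = FALSE]
  sub_samples <- samples[idx, , drop = FALSE]
  kept <- suppressWarnings(filter_low_counts(sub_counts, settings))
  if (nrow(kept) == 0) return(0L)
  dispersions <- NULL
  if (residual_dispersion) {
    sf <- size_factors(kept)
    dispersions <- residual_mom_dispersion(kept, sf, sub_samples, settings,
                                           include_colony = include_colony)
    fit <- nb_fit_all(kept, sub_samples, settings, factors = sf,
                      dispersions = dispersions,
                      include_colony = include_colony)
    de <- de_result_from_fit(fit, contrast, settings)
  } else {
    de <- nb_wald(kept, sub_samples, settings, contrast,
                  include_colony = include_colony)
  }
  sum(de$significant, na.rm = TRUE)
}

# Method-of-moments dispersion from the residuals of the full design
# (treatment + colony when colonies are replicated across arms). Used by
# the colony-matched diagnostic, where colony is a blocking factor and the
# treatment-cell estimator would absorb between-colony variance into the
# dispersion.
residual_mom_dispersion <- function(counts, factors, samples, settings,
                                    include_colony = TRUE) {
  y <- sweep(counts, 2, factors, "/")
  smp <- samples
  if (!include_colony) smp$colony <- 1
  X <- de_model_matrix(smp)
  n <- ncol(y)
  p <- ncol(X)
  if (n - p < 1)
    return(estimate_dispersion(counts, factors, samples, settings))
  qrx <- qr(X)
  resid <- t(qr.resid(qrx, t(y)))
  v <- rowSums(resid^2) / (n - p)
  m <- rowMeans(y)
  alpha <- ifelse(m > 0, (v - m) / m^2, settings$dispersion_floor)
  alpha <- pmin(pmax(alpha, settings$dispersion_floor),
                settings$dispersion_cap)
  setNames(alpha, rownames(counts))
}

#' Replicate-balance subsampling of the DE analysis
#'
#' Repeatedly draws `target_n` control and `target_n` chronic-treatment
#' samples (unique joint subsets when requested), reruns the full DE
#' pipeline on each subset, and records the number of significant genes.
#' Each acute contrast's DE count (from the full design, where acute groups
#' already have `target_n` replicates) is then compared against that
#' distribution with an add-one permutation p-value:
#' `p = (1 + #(iterations >= acute count)) / (n_iterations + 1)`.
#'
#' @param counts filtered or raw count matrix (the filter is re-applied per
#'   subset).
#' @param samples sample table aligned to columns.
#' @param chronic_contrast chronic treatment label to subsample against the
#'   control.
#' @param acute_contrasts acute treatment labels to compare (optional).
#' @param settings a [de_settings()].
#' @param config a [subsample_config()].
#' @return list: `de_counts` (per iteration), `subsets` (canonical joint
#'   signatures), `median`, and per-acute-contrast observed counts and
#'   permutation p-values.
#' @export
balanced_subsample_de <- function(counts, samples, chronic_contrast,
                                  acute_contrasts = NULL,
                                  settings = de_settings(),
                                  config = subsample_config()) {
  ctrl_idx <- which(samples$treatment == "control")
  chr_idx <- which(samples$treatment == chronic_contrast)
  t_n <- config$target_n
  if (length(ctrl_idx) < t_n || length(chr_idx) < t_n)
    stopf("need at least %d replicates in control and %s", t_n,
          chronic_contrast)
  n_distinct <- choose(length(ctrl_idx), t_n) * choose(length(chr_idx), t_n)
  if (config$unique_subsets && config$n_iterations > n_distinct)
    stopf("only %g distinct joint subsets exist; lower n_iterations",
          n_distinct)

  with_seed(config$seed, {
    seen <- character(0)
    de_counts <- integer(config$n_iterations)
    sigs <- character(config$n_iterations)
    for (b in seq_len(config$n_iterations)) {
      for (attempt in seq_len(1000)) {
        sc <- sort(sample(ctrl_idx, t_n))
        st <- sort(sample(chr_idx, t_n))
        sig <- paste(c(sc, "|", st), collapse = ",")
        if (!config$unique_subsets || !(sig %in% seen)) break
        if (attempt == 1000)
          stopf("could not find a fresh subset after 1000 attempts")
      }
      seen <- c(seen, sig)
      sigs[b] <- sig
      idx <- c(sc, st)
      stopifnot(all(samples$treatment[idx] %in%
                      c("control", chronic_contrast)))
      de_counts[b] <- de_count_on_subset(counts, samples, idx,
                                         chronic_contrast, settings)
    }
    acute <- NULL
    if (length(acute_contrasts)) {
      acute <- lapply(acute_contrasts, function(tr) {
        idx <- which(samples$treatment %in% c("control", tr))
        cnt <- de_count_on_subset(counts, samples, idx, tr, settings)
        list(contrast = tr, de_count = cnt,
             p = (1 + sum(de_counts >= cnt)) / (config$n_iterations + 1))
      })
      names(acute) <- acute_contrasts
    }
    list(chronic_contrast = chronic_contrast, de_counts = de_counts,
         subsets = sigs, median = median(de_counts), acute = acute,
         config = config)
  })
}

summarize_counts <- function(counts) {
  list(de_counts = counts,
       median = median(counts),
       skewness = tryCatch(skewness(counts), error = function(e) NA_real_))
}

#' Colony-matched versus colony-mismatched resampling
#'
#' Emulates the design diagnostic for genetic-background confounding: in
#' mismatched mode, control samples are drawn from one random half of the
#' source colonies and treatment samples from the complementary half, so
#' colony is fully confounded with the comparison; in matched mode both
#' arms come from the same random colony subset. Each iteration reruns the
#' DE pipeline *without* the colony covariate (it is aliased with the arms
#' in the mismatched case) and records the number of significant genes; the
#' two count distributions are summarized and compared with a
#' Kolmogorov-Smirnov test.
#'
#' @param counts count matrix.
#' @param samples sample table aligned to columns.
#' @param treatment treatment label compared against the control.
#' @param settings a [de_settings()].
#' @param config a [confound_config()].
#' @param modes which resampling modes to run; the Kolmogorov-Smirnov
#'   comparison requires both.
#' @return list: `matched` and `mismatched` summaries (counts, median,
#'   skewness) and `ks` (D, p; `NULL` unless both modes ran).
#' @export
colony_confound_resample <- function(counts, samples, treatment,
                                     settings = de_settings(),
                                     config = confound_config(),
                                     modes = c("matched", "mismatched")) {
  modes <- match.arg(modes, several.ok = TRUE)
  cpa <- config$colonies_per_arm
  ctrl <- samples$treatment == "control"
  trt <- samples$treatment == treatment
  usable <- sort(intersect(unique(samples$colony[ctrl]),
                           unique(samples$colony[trt])))
  need <- if ("mismatched" %in% modes) 2 * cpa else cpa
  if (length(usable) < need)
    stopf("need %d colonies with samples in both arms; have %d",
          need, length(usable))

  draw_counts <- function(mode) {
    vapply(seq_len(config$n_iterations), function(b) {
      if (mode == "matched") {
        half_a <- sample(usable, cpa)
        half_b <- half_a
      } else {
        pick <- sample(usable, 2 * cpa)
        half_a <- pick[seq_len(cpa)]
        half_b <- pick[cpa + seq_len(cpa)]
      }
      idx <- c(which(ctrl & samples$colony %in% half_a),
               which(trt & samples$colony %in% half_b))
      stopifnot(all(samples$treatment[idx] %in% c("control", treatment)))
      # the matched design can (and does) model colony as a blocking
      # factor, with dispersion from full-design residuals; the mismatched
      # design cannot, since colony is aliased with the comparison
      de_count_on_subset(counts, samples, idx, treatment, settings,
                         include_colony = (mode == "matched"),
                         residual_dispersion = (mode == "matched"))
    }, integer(1))
  }

  with_seed(config$seed, {
    out <- list(config = config)
    for (m in modes) out[[m]] <- summarize_counts(draw_counts(m))
    if (all(c("matched", "mismatched") %in% modes))
      out$ks <- ks_two_sample(out$matched$de_counts,
                              out$mismatched$de_counts)
    out
  })
}
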