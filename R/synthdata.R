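#' Configuration for the synthetic exposure-study generator
#'
#' Builds the parameter set that defines the emulated study: ten source
#' colonies, seven treatments (control plus three compounds under acute and
#' chronic exposure schemes), negative-binomial gene counts with colony
#' blocking effects, a shared acute-response gene set that is mostly
#' upregulated with large amplitudes, a shared chronic set containing a few
#' strongly downregulated immune-like genes, and extra replicate variance in
#' acute treatments restricted to the genes that actually respond.
#'
#' @param n_genes number of genes to simulate.
#' @param colonies number of source (queenright) colonies; used as a blocking
#'   factor in all downstream models.
#' @param replicates_chronic_control microcolonies per treatment for the
#'   control and each chronic treatment.
#' @param replicates_acute microcolonies per acute treatment.
#' @param compounds compound labels; each is crossed with both schemes.
#' @param library_size_range total counts per sample are drawn log-uniformly
#'   from this range.
#' @param baseline_log2_mean `c(location, scale)` of the normal distribution
#'   of per-gene baseline log2 relative abundance.
#' @param dispersion_trend `c(alpha0, alpha1)` of the mean-dispersion trend
#'   `alpha(mu) = alpha0 + alpha1 / mu`.
#' @param colony_effect_sd standard deviation (log2 scale) of per-gene,
#'   per-colony expression offsets.
#' @param shared_acute_set_size number of genes responding to every acute
#'   treatment.
#' @param acute_up_fraction fraction of the shared acute set that is
#'   upregulated; the count of upregulated genes is `round half up` of
#'   `fraction * size`.
#' @param shared_chronic_set_size number of genes responding to every chronic
#'   treatment (all downregulated).
#' @param chronic_strong_down_lfc log2 fold change of the strongly
#'   downregulated (antimicrobial-peptide-like) chronic genes; -5 is 32-fold.
#' @param chronic_strong_down_n how many shared chronic genes carry
#'   `chronic_strong_down_lfc`; the rest carry `chronic_base_magnitude`.
#' @param chronic_base_magnitude |log2 fold change| of the remaining shared
#'   chronic genes.
#' @param amplitude_ratio_acute_over_chronic the mean |log2 fold change| of
#'   the shared acute set is constructed to be exactly this multiple of the
#'   shared chronic set's mean |log2 fold change|.
#' @param acute_extra_sd_factor multiplicative inflation of the replicate
#'   standard deviation (on the variance-stabilized scale) of responding
#'   genes in acute treatments relative to the chronic side.
#' @param acute_specific_sizes,chronic_specific_sizes named integer vectors
#'   (one entry per compound) of additional treatment-specific response
#'   genes.
#' @param acute_specific_lfc_range,chronic_specific_lfc_range ranges of
#'   |log2 fold change| for treatment-specific genes.
#' @param acute_specific_up_prob probability that a treatment-specific acute
#'   gene is upregulated.
#' @param chronic_specific_up_prob probability that a treatment-specific
#'   chronic gene is upregulated.
#' @param seed integer seed; identical configurations produce byte-identical
#'   outputs.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_genes = 2000,
                         colonies = 10,
                         replicates_chronic_control = 10,
                         replicates_acute = 8,
                         compounds = c("acetamiprid", "clothianidin",
                                       "sulfoxaflor"),
                         library_size_range = c(5e5, 2e6),
                         baseline_log2_mean = c(location = 5, scale = 2),
                         dispersion_trend = c(alpha0 = 0.01, alpha1 = 0.5),
                         colony_effect_sd = 0.3,
                         shared_acute_set_size = 61,
                         acute_up_fraction = 0.91,
                         shared_chronic_set_size = 20,
                         chronic_strong_down_lfc = -5,
                         chronic_strong_down_n = 4,
                         chronic_base_magnitude = 1.75,
                         amplitude_ratio_acute_over_chronic = 2.7,
                         acute_extra_sd_factor = 1.2,
                         acute_specific_sizes = c(acetamiprid = 100,
                                                  clothianidin = 220,
                                                  sulfoxaflor = 8),
                         chronic_specific_sizes = c(acetamiprid = 12,
                                                    clothianidin = 60,
                                                    sulfoxaflor = 8),
                         acute_specific_lfc_range = c(1.5, 5),
                         chronic_specific_lfc_range = c(0.8, 1.4),
                         acute_specific_up_prob = 0.9,
                         chronic_specific_up_prob = 0.3,
                         seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be positive")
  if (!is_count(colonies) || colonies < 1) stopf("colonies must be positive")
  if (!is_count(replicates_chronic_control) || replicates_chronic_control < 1)
    stopf("replicates_chronic_control must be positive")
  if (!is_count(replicates_acute) || replicates_acute < 1)
    stopf("replicates_acute must be positive")
  if (length(compounds) < 1 || anyDuplicated(compounds))
    stopf("compounds must be unique labels")
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stopf("library_size_range must be an increasing pair of positive reals")
  if (any(dispersion_trend < 0))
    stopf("dispersion_trend components must be non-negative")
  if (colony_effect_sd < 0) stopf("colony_effect_sd must be non-negative")
  if (acute_up_fraction < 0 || acute_up_fraction > 1)
    stopf("acute_up_fraction must lie in [0, 1]")
  if (chronic_strong_down_lfc >= 0)
    stopf("chronic_strong_down_lfc must be negative")
  if (amplitude_ratio_acute_over_chronic <= 0)
    stopf("amplitude_ratio_acute_over_chronic must be positive")
  if (acute_extra_sd_factor <= 0)
    stopf("acute_extra_sd_factor must be positive")
  if (chronic_strong_down_n > shared_chronic_set_size)
    stopf("chronic_strong_down_n cannot exceed shared_chronic_set_size")

  norm_sizes <- function(sizes, what) {
    if (length(sizes) == 1 && is.null(names(sizes)))
      sizes <- setNames(rep(sizes, length(compounds)), compounds)
    if (!all(compounds %in% names(sizes)))
      stopf("%s must be named for every compound", what)
    sizes <- sizes[compounds]
    if (any(sizes < 0) || any(sizes != round(sizes)))
      stopf("%s must be non-negative integers", what)
    sizes
  }
  acute_specific_sizes <- norm_sizes(acute_specific_sizes,
                                     "acute_specific_sizes")
  chronic_specific_sizes <- norm_sizes(chronic_specific_sizes,
                                       "chronic_specific_sizes")

  total_de <- shared_acute_set_size + shared_chronic_set_size +
    sum(acute_specific_sizes) + sum(chronic_specific_sizes)
  if (total_de > n_genes)
    stopf("designated gene sets (%d genes) exceed n_genes (%d)",
          total_de, n_genes)

  cfg <- list(
    n_genes = as.integer(n_genes),
    colonies = as.integer(colonies),
    replicates_chronic_control = as.integer(replicates_chronic_control),
    replicates_acute = as.integer(replicates_acute),
    compounds = compounds,
    library_size_range = library_size_range,
    baseline_log2_mean = c(location = unname(baseline_log2_mean[1]),
                           scale = unname(baseline_log2_mean[2])),
    dispersion_trend = c(alpha0 = unname(dispersion_trend[1]),
                         alpha1 = unname(dispersion_trend[2])),
    colony_effect_sd = colony_effect_sd,
    shared_acute_set_size = as.integer(shared_acute_set_size),
    acute_up_fraction = acute_up_fraction,
    shared_chronic_set_size = as.integer(shared_chronic_set_size),
    chronic_strong_down_lfc = chronic_strong_down_lfc,
    chronic_strong_down_n = as.integer(chronic_strong_down_n),
    chronic_base_magnitude = chronic_base_magnitude,
    amplitude_ratio_acute_over_chronic = amplitude_ratio_acute_over_chronic,
    acute_extra_sd_factor = acute_extra_sd_factor,
    acute_specific_sizes = acute_specific_sizes,
    chronic_specific_sizes = chronic_specific_sizes,
    acute_specific_lfc_range = acute_specific_lfc_range,
    chronic_specific_lfc_range = chronic_specific_lfc_range,
    acute_specific_up_prob = acute_specific_up_prob,
    chronic_specific_up_prob = chronic_specific_up_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' A configuration with no true effects anywhere
#'
#' Convenience wrapper producing a global-null design (no responding genes,
#' no colony effects) used for calibration checks of the DE engine and the
#' resampling diagnostics.
#'
#' @param ... overrides passed on to [synth_config()].
#' @return a `synth_config`.
#' @export
null_synth_config <- function(...) {
  args <- list(...)
  defaults <- list(shared_acute_set_size = 0,
                   shared_chronic_set_size = 0,
                   chronic_strong_down_n = 0,
                   acute_specific_sizes = c(acetamiprid = 0,
                                            clothianidin = 0,
                                            sulfoxaflor = 0),
                   chronic_specific_sizes = c(acetamiprid = 0,
                                              clothianidin = 0,
                                              sulfoxaflor = 0),
                   colony_effect_sd = 0)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(synth_config, args)
}

# Ordered treatment labels for a configuration; control first.
treatment_levels <- function(config) {
  c("control",
    paste(rep(config$compounds, each = 2), c("acute", "chronic"), sep = "_"))
}

# One row per microcolony (= sequencing sample) with design factors.
build_sample_table <- function(config) {
  rows <- list()
  for (tr in treatment_levels(config)) {
    if (tr == "control") {
      compound <- "none"; scheme <- "none"
      n <- config$replicates_chronic_control
    } else {
      parts <- strsplit(tr, "_", fixed = TRUE)[[1]]
      compound <- paste(parts[-length(parts)], collapse = "_")
      scheme <- parts[length(parts)]
      n <- if (scheme == "acute") config$replicates_acute
           else config$replicates_chronic_control
    }
    rows[[tr]] <- data.frame(
      sample_id = sprintf("%s_r%02d", tr, seq_len(n)),
      treatment = tr,
      compound = compound,
      scheme = scheme,
      colony = as.integer(((seq_len(n) - 1) %% config$colonies) + 1),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact mean and variance of log2(X + pseudocount), X ~ NB(mu, size = 1/alpha),
# by summation of the probability mass function. Used to calibrate the
# acute replicate-variance inflation on the variance-stabilized scale.
nb_log2_moments <- function(mu, alpha, pseudocount = 1) {
  size <- 1 / alpha
  kmax <- min(max(20, qnbinom(1 - 1e-9, mu = mu, size = size)), 2e5)
  k <- 0:kmax
  pr <- dnbinom(k, mu = mu, size = size)
  v <- log2(k + pseudocount)
  m1 <- sum(pr * v)
  m2 <- sum(pr * v^2)
  c(mean = m1, var = max(m2 - m1^2, 0))
}

# True log2-fold-change matrix (genes x non-control treatments) plus set
# membership labels. Deterministic given the RNG state.
build_ground_truth <- function(config) {
  tl <- treatment_levels(config)
  trt <- setdiff(tl, "control")
  lfc <- matrix(0, nrow = config$n_genes, ncol = length(trt),
                dimnames = list(NULL, trt))
  set <- rep("null", config$n_genes)
  cursor <- 0
  take <- function(n) {
    idx <- cursor + seq_len(n)
    cursor <<- cursor + n
    idx
  }

  acute_cols <- grep("_acute$", trt, value = TRUE)
  chronic_cols <- grep("_chronic$", trt, value = TRUE)

  # shared chronic set first defines the amplitude reference
  chronic_mag <- numeric(0)
  if (config$shared_chronic_set_size > 0) {
    n_strong <- config$chronic_strong_down_n
    chronic_mag <- c(rep(abs(config$chronic_strong_down_lfc), n_strong),
                     rep(config$chronic_base_magnitude,
                         config$shared_chronic_set_size - n_strong))
  }
  ref_mean <- if (length(chronic_mag)) mean(chronic_mag) else 1

  # shared acute set: tight magnitude distribution rescaled so that its mean
  # is exactly amplitude_ratio x the shared chronic mean (construction).
  if (config$shared_acute_set_size > 0) {
    n <- config$shared_acute_set_size
    idx <- take(n)
    set[idx] <- "shared_acute"
    mag <- abs(rnorm(n, mean = 1, sd = 0.05))
    mag <- mag * (config$amplitude_ratio_acute_over_chronic * ref_mean /
                    mean(mag))
    n_up <- min(n, floor(config$acute_up_fraction * n + 0.5))
    sign <- rep(-1, n)
    sign[sample.int(n, n_up)] <- 1
    for (cc in acute_cols) lfc[idx, cc] <- sign * mag
  }

  # compound-specific acute genes
  for (cmp in config$compounds) {
    n <- config$acute_specific_sizes[[cmp]]
    if (n == 0) next
    idx <- take(n)
    set[idx] <- paste0("acute_specific_", cmp)
    mag <- runif(n, config$acute_specific_lfc_range[1],
                 config$acute_specific_lfc_range[2])
    sign <- ifelse(runif(n) < config$acute_specific_up_prob, 1, -1)
    # downregulation amplitudes are kept moderate (mirrors the asymmetry of
    # the acute response, which is dominated by induction)
    mag[sign < 0] <- pmin(mag[sign < 0],
                          mean(config$acute_specific_lfc_range))
    lfc[idx, paste0(cmp, "_acute")] <- sign * mag
  }

  if (config$shared_chronic_set_size > 0) {
    idx <- take(config$shared_chronic_set_size)
    set[idx] <- "shared_chronic"
    for (cc in chronic_cols) lfc[idx, cc] <- -chronic_mag
  }

  for (cmp in config$compounds) {
    n <- config$chronic_specific_sizes[[cmp]]
    if (n == 0) next
    idx <- take(n)
    set[idx] <- paste0("chronic_specific_", cmp)
    mag <- runif(n, config$chronic_specific_lfc_range[1],
                 config$chronic_specific_lfc_range[2])
    sign <- ifelse(runif(n) < config$chronic_specific_up_prob, 1, -1)
    lfc[idx, paste0(cmp, "_chronic")] <- sign * mag
  }

  list(lfc = lfc, set = set)
}

#' Generate synthetic gene counts, sample metadata, and ground truth
#'
#' Draws a gene x sample matrix of negative-binomial counts whose expected
#' value for gene g in sample j is the sample's library size times the
#' relative abundance `2^(baseline_g + colony_effect + true_lfc)`, with
#' dispersion following the configured mean-dispersion trend. Genes that
#' truly respond in an acute treatment additionally receive log-normal
#' replicate noise calibrated so that their replicate standard deviation on
#' the variance-stabilized scale is `acute_extra_sd_factor` times the
#' chronic-side expectation.
#'
#' @param config a [synth_config()].
#' @return list with elements `counts` (integer matrix, genes x samples),
#'   `samples` (data frame: sample_id, treatment, compound, scheme, colony)
#'   and `truth` (list: `lfc` matrix of true log2 fold changes vs control,
#'   `set` membership label per gene, `gene_id`).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    samples <- build_sample_table(config)
    truth <- build_ground_truth(config)
    gene_id <- sprintf("g%04d", seq_len(config$n_genes))

    loc <- config$baseline_log2_mean[["location"]]
    scl <- config$baseline_log2_mean[["scale"]]
    baseline <- rnorm(config$n_genes, loc, scl)
    # keep strongly shifted genes estimable: strong inductions start low,
    # strong repressions start high
    max_lfc <- apply(truth$lfc, 1, max)
    min_lfc <- apply(truth$lfc, 1, min)
    strong_up <- max_lfc >= 3
    strong_dn <- min_lfc <= -3 & !strong_up
    if (any(strong_up))
      baseline[strong_up] <- rnorm(sum(strong_up), loc - 1.5, scl / 2)
    if (any(strong_dn))
      baseline[strong_dn] <- rnorm(sum(strong_dn), loc + 1.5, scl / 2)

    colony_eff <- matrix(rnorm(config$n_genes * config$colonies,
                               0, config$colony_effect_sd),
                         nrow = config$n_genes)

    lsr <- config$library_size_range
    lib <- 2^runif(nrow(samples), log2(lsr[1]), log2(lsr[2]))

    tl <- treatment_levels(config)
    lfc_full <- cbind(control = 0, truth$lfc)[, tl, drop = FALSE]

    log2w <- baseline + colony_eff[, samples$colony, drop = FALSE] +
      lfc_full[, samples$treatment, drop = FALSE]
    w <- 2^log2w
    mu <- sweep(w, 2, colSums(w), "/")
    mu <- sweep(mu, 2, lib, "*")

    # Acute replicate-variance inflation. Genes that respond to any acute
    # treatment are intrinsically noisier across the whole acute scheme:
    # in every acute treatment their total replicate variance of
    # log2(count+1) (counting noise + colony effects + sigma^2) is driven
    # to factor^2 x the variance their *baseline* expression level would
    # have in that same sample context (exact NB moments; clamped at zero
    # when mean shifts alone already exceed the target).
    f2 <- config$acute_extra_sd_factor^2
    acute_trs <- grep("_acute$", tl, value = TRUE)
    responders <- if (length(acute_trs))
      which(rowSums(truth$lfc[, acute_trs, drop = FALSE] != 0) > 0)
    else integer(0)
    if (f2 > 1 && length(responders)) {
      a0 <- config$dispersion_trend[["alpha0"]]
      a1 <- config$dispersion_trend[["alpha1"]]
      v_colony <- config$colony_effect_sd^2
      lib_ref <- sqrt(lsr[1] * lsr[2])
      for (tr in acute_trs) {
        genes <- responders
        cols <- which(samples$treatment == tr)
        w_t <- 2^(baseline + lfc_full[, tr])
        sum_wt <- sum(w_t)
        mu_t <- lib_ref * w_t / sum_wt
        # baseline expression in the same (acute) composition context
        mu_b <- lib_ref * 2^baseline / sum_wt
        sig <- vapply(genes, function(g) {
          va <- nb_log2_moments(mu_t[g], a0 + a1 / mu_t[g])[["var"]]
          vb <- nb_log2_moments(mu_b[g], a0 + a1 / mu_b[g])[["var"]]
          sqrt(max(f2 * (vb + v_colony) - (va + v_colony), 0))
        }, numeric(1))
        eps <- matrix(rnorm(length(genes) * length(cols), 0, 1),
                      nrow = length(genes)) * sig
        # centre the log-normal factor so expected counts are unchanged
        eps <- eps - (sig^2) * log(2) / 2
        mu[genes, cols] <- mu[genes, cols] * 2^eps
      }
    }

    alpha <- config$dispersion_trend[["alpha0"]] +
      config$dispersion_trend[["alpha1"]] / mu
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = 1 / as.vector(alpha)),
                     nrow = config$n_genes,
                     dimnames = list(gene_id, samples$sample_id))
    storage.mode(counts) <- "integer"

    list(counts = counts,
         samples = samples,
         truth = list(lfc = `rownames<-`(truth$lfc, gene_id),
                      set = setNames(truth$set, gene_id),
                      gene_id = gene_id))
  })
}

#' Default treatment hazard ratios for the survival generator
#'
#' Chosen so that, at the default baseline hazard, expected mortality is
#' roughly 54% for acute clothianidin (over its two-day exposure window) and
#' 29% for chronic clothianidin over the full 14 days, with milder effects
#' for the other compounds.
#'
#' @param config a [synth_config()].
#' @return named vector of hazard ratios per treatment.
#' @export
default_hazard_ratios <- function(config) {
  hr <- setNames(rep(1, length(treatment_levels(config))),
                 treatment_levels(config))
  set_if <- function(hr, name, value) {
    if (name %in% names(hr)) hr[name] <- value
    hr
  }
  hr <- set_if(hr, "clothianidin_acute", 99)
  hr <- set_if(hr, "clothianidin_chronic", 7.5)
  hr <- set_if(hr, "acetamiprid_acute", 20)
  hr <- set_if(hr, "acetamiprid_chronic", 2)
  hr <- set_if(hr, "sulfoxaflor_acute", 30)
  hr <- set_if(hr, "sulfoxaflor_chronic", 3)
  hr
}

#' Generate individual-level survival records
#'
#' Event times are exponential with treatment-specific hazards. Acute-
#' treatment individuals are at baseline (control) hazard until their
#' exposure window opens two days before the horizon, and at elevated hazard
#' only within that window; chronic individuals are at baseline hazard for
#' the two-day adjustment period and at elevated hazard afterwards. Records
#' are censored at the horizon.
#'
#' @param config a [synth_config()].
#' @param hazard_ratios named treatment -> hazard ratio mapping; missing
#'   treatments default to 1.
#' @param horizon_days length of the experiment in days.
#' @param baseline_hazard control (per-day) hazard.
#' @param bees_per_microcolony individuals per microcolony.
#' @return data frame of records: individual, microcolony, treatment,
#'   time_days, event (1 = death, 0 = censored), window_start.
#' @export
generate_survival <- function(config,
                              hazard_ratios = default_hazard_ratios(config),
                              horizon_days = 14,
                              baseline_hazard = 0.0037,
                              bees_per_microcolony = 6) {
  stopifnot(inherits(config, "synth_config"))
  if (!is_count(horizon_days) || horizon_days < 1)
    stopf("horizon_days must be a positive integer")
  if (any(hazard_ratios <= 0)) stopf("hazard ratios must be positive")
  if (baseline_hazard <= 0) stopf("baseline_hazard must be positive")

  with_seed(stage_seed(config$seed, 2L), {
    samples <- build_sample_table(config)
    recs <- lapply(seq_len(nrow(samples)), function(i) {
      tr <- samples$treatment[i]
      hr <- if (tr %in% names(hazard_ratios)) hazard_ratios[[tr]] else 1
      scheme <- samples$scheme[i]
      n <- bees_per_microcolony
      h0 <- baseline_hazard
      if (scheme == "acute") {
        wstart <- horizon_days - 2
        t1 <- rexp(n, h0)
        t2 <- rexp(n, h0 * hr)
        time <- ifelse(t1 < wstart, t1, wstart + t2)
      } else if (scheme == "chronic") {
        wstart <- 0
        adj <- 2 # adjustment period before exposure begins
        t1 <- rexp(n, h0)
        t2 <- rexp(n, h0 * hr)
        time <- ifelse(t1 < adj, t1, adj + t2)
      } else {
        wstart <- 0
        time <- rexp(n, h0)
      }
      event <- as.integer(time <= horizon_days)
      time <- pmin(time, horizon_days)
      data.frame(
        individual = sprintf("%s_b%d", samples$sample_id[i], seq_len(n)),
        microcolony = samples$sample_id[i],
        treatment = tr,
        time_days = time,
        event = event,
        window_start = wstart,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

#' Default per-day intake slopes (mL per bee per day of exposure)
#'
#' Chronic clothianidin reduces daily intake by 0.063 mL per exposure day
#' relative to the control; acute clothianidin drops steeply (0.51 mL/day)
#' within its two-day window. Other treatments do not alter intake.
#'
#' @param config a [synth_config()].
#' @return named vector of slopes per treatment.
#' @export
default_intake_slopes <- function(config) {
  sl <- setNames(rep(0, length(treatment_levels(config))),
                 treatment_levels(config))
  if ("clothianidin_chronic" %in% names(sl))
    sl["clothianidin_chronic"] <- -0.063
  if ("clothianidin_acute" %in% names(sl))
    sl["clothianidin_acute"] <- -0.51
  sl
}

#' Generate per-microcolony food-intake series
#'
#' Average daily intake per bee measured every two days over a 14-day
#' experiment: baseline + colony offset + treatment slope x day (chronic) or
#' x days-into-window (acute) + Gaussian noise.
#'
#' @param config a [synth_config()].
#' @param slopes named treatment -> slope mapping (mL per bee per day per
#'   exposure day, relative to control); missing treatments default to 0.
#' @param baseline_ml control intake, mL per bee per day.
#' @param colony_sd standard deviation of colony offsets.
#' @param noise_sd measurement noise standard deviation; 0 gives exact
#'   linear series.
#' @param days measurement days.
#' @return data frame: microcolony, colony, treatment, scheme, day,
#'   intake_ml_per_bee.
#' @export
generate_intake <- function(config,
                            slopes = default_intake_slopes(config),
                            baseline_ml = 1.6,
                            colony_sd = 0.08,
                            noise_sd = 0.08,
                            days = seq(2, 14, by = 2)) {
  stopifnot(inherits(config, "synth_config"))
  if (baseline_ml <= 0) stopf("baseline_ml must be positive")
  with_seed(stage_seed(config$seed, 3L), {
    samples <- build_sample_table(config)
    colony_off <- rnorm(config$colonies, 0, colony_sd)
    grid <- merge(samples, data.frame(day = days), by = NULL)
    sl <- ifelse(grid$treatment %in% names(slopes),
                 unname(slopes[grid$treatment]), 0)
    exposure_day <- ifelse(grid$scheme == "acute",
                           pmax(grid$day - 12, 0), grid$day)
    intake <- baseline_ml + colony_off[grid$colony] + sl * exposure_day +
      rnorm(nrow(grid), 0, noise_sd)
    if (any(intake < 0))
      warning("negative intake values generated; consider gentler slopes")
    out <- data.frame(microcolony = grid$sample_id,
                      colony = grid$colony,
                      treatment = grid$treatment,
                      scheme = grid$scheme,
                      day = grid$day,
                      intake_ml_per_bee = intake,
                      stringsAsFactors = FALSE)
    out <- out[order(out$microcolony, out$day), ]
    rownames(out) <- NULL
    out
  })
}
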