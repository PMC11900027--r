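#' Configuration of a full pipeline run
#'
#' Exactly one data source: either `synth` (a [synth_config()]) or
#' `input_paths` (named list with `counts`, `samples`, and optionally
#' `truth`, `survival`, `intake` files written by this package's writers).
#'
#' @param outdir output directory (created if missing).
#' @param synth a [synth_config()] or `NULL`.
#' @param input_paths named list of input files or `NULL`.
#' @param settings a [de_settings()].
#' @param overlap_B,overlap_seed iterations and seed of the overlap null.
#' @param subsample a [subsample_config()] or `NULL` to skip.
#' @param confound a [confound_config()] or `NULL` to skip.
#' @param seed global seed; per-stage seeds are derived deterministically
#'   from it (fixed offsets), so stages can be rerun in isolation.
#' @param verbose print stage progress.
#' @return list of class `run_config`.
#' @export
run_config <- function(outdir,
                       synth = synth_config(),
                       input_paths = NULL,
                       settings = de_settings(),
                       overlap_B = 10000,
                       overlap_seed = NULL,
                       subsample = subsample_config(n_iterations = 20),
                       confound = confound_config(n_iterations = 20),
                       seed = 1,
                       verbose = TRUE) {
  if (is.null(synth) == is.null(input_paths))
    stopf("exactly one of synth / input_paths must be given")
  structure(list(outdir = outdir, synth = synth, input_paths = input_paths,
                 settings = settings, overlap_B = overlap_B,
                 overlap_seed = if (is.null(overlap_seed))
                   stage_seed(seed, 4L) else overlap_seed,
                 subsample = subsample, confound = confound,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

pipeline_stage <- function(name, verbose, expr) {
  if (verbose) message("[stage] ", name)
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s (partial outputs retained)", name,
          conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Stages: generate or load data; differential expression per treatment
#' (negative-binomial Wald, treatment + colony design); VST and PCA;
#' multi-set overlap statistics of the acute and chronic DE sets;
#' exposure-scheme contrast statistics; resampling diagnostics; survival,
#' intake, and dose accounting; report. Every output file is listed in a
#' manifest with its MD5 hash; identical configurations (including seeds)
#' give identical hashes.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `manifest` (data frame: file, md5) and
#'   `results` (per-stage result objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  verbose <- config$verbose
  settings <- config$settings
  results <- list()
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)

  dat <- pipeline_stage("data", verbose, {
    if (!is.null(config$synth)) {
      cfg <- config$synth
      cfg$seed <- stage_seed(config$seed, 1L)
      d <- generate_counts(cfg)
      d$survival <- generate_survival(cfg)
      d$intake <- generate_intake(cfg)
      add_file(write_counts_tsv(d$counts, file.path(outdir, "counts.tsv")))
      add_file(write_samples_csv(d$samples, file.path(outdir,
                                                      "samples.csv")))
      add_file(write_truth_tsv(d$truth, file.path(outdir, "truth.tsv")))
      add_file(write_table_fixed(d$survival,
                                 file.path(outdir, "survival.csv"), ","))
      add_file(write_table_fixed(d$intake,
                                 file.path(outdir, "intake.csv"), ","))
      d
    } else {
      p <- config$input_paths
      d <- list(counts = read_counts_tsv(p$counts),
                samples = read_samples_csv(p$samples))
      if (!is.null(p$truth)) d$truth <- read_truth_tsv(p$truth)
      if (!is.null(p$survival))
        d$survival <- read.table(p$survival, header = TRUE, sep = ",",
                                 stringsAsFactors = FALSE)
      if (!is.null(p$intake))
        d$intake <- read.table(p$intake, header = TRUE, sep = ",",
                               stringsAsFactors = FALSE)
      d
    }
  })
  results$data <- dat
  samples <- dat$samples
  contrasts <- setdiff(unique(samples$treatment), "control")

  de <- pipeline_stage("de", verbose, {
    kept <- filter_low_counts(dat$counts, settings)
    sf <- size_factors(kept)
    tables <- nb_wald_all(kept, samples, settings)
    for (tr in names(tables))
      add_file(write_de_tsv(tables[[tr]],
                            file.path(outdir, paste0("de_", tr, ".tsv"))))
    vst <- vst_transform(kept, sf, settings)
    pca <- pca_samples(vst)
    pca_df <- data.frame(sample_id = rownames(pca$coordinates),
                         pca$coordinates[, seq_len(min(4,
                           ncol(pca$coordinates))), drop = FALSE],
                         stringsAsFactors = FALSE)
    add_file(write_table_fixed(pca_df, file.path(outdir, "pca.csv"), ","))
    list(kept = kept, sf = sf, tables = tables, vst = vst, pca = pca)
  })
  results$de <- de

  overlap <- pipeline_stage("overlap", verbose, {
    sig_sets <- lapply(de$tables, function(t) t$gene_id[t$significant])
    pool <- rownames(de$kept)
    out <- list()
    rows <- list()
    for (scheme in c("acute", "chronic")) {
      nm <- grep(paste0("_", scheme, "$"), names(sig_sets), value = TRUE)
      sets <- sig_sets[nm]
      if (length(sets) < 2 || any(lengths(sets) == 0)) next
      coll <- gene_set_collection(sets, pool)
      res <- overlap_test(coll, B = config$overlap_B,
                          seed = stage_seed(config$overlap_seed,
                                            match(scheme,
                                                  c("acute", "chronic"))))
      out[[scheme]] <- list(test = res, euler = euler_regions(coll))
      rows[[scheme]] <- data.frame(
        comparison = scheme, observed = res$observed,
        expected = res$expected, expected_analytic = res$expected_analytic,
        expected_se = res$expected_se, fold = res$fold_enrichment,
        p_value = res$p_value, B = res$n_iterations,
        pool_size = res$pool_size, stringsAsFactors = FALSE)
      eu <- data.frame(signature = names(out[[scheme]]$euler),
                       count = as.integer(out[[scheme]]$euler),
                       stringsAsFactors = FALSE)
      add_file(write_table_fixed(eu,
        file.path(outdir, paste0("euler_", scheme, ".csv")), ","))
    }
    if (length(rows))
      add_file(write_table_fixed(do.call(rbind, rows),
                                 file.path(outdir, "overlap.csv"), ","))
    out
  })
  results$overlap <- overlap

  contrast <- pipeline_stage("contrast", verbose, {
    rows <- list()
    push <- function(statistic, value, df = NA, p = NA, method)
      rows[[length(rows) + 1]] <<- data.frame(
        statistic = statistic, value = value, df = df, p = p,
        method = method, stringsAsFactors = FALSE)
    acute_clo <- de$tables[["clothianidin_acute"]]
    chronic_clo <- de$tables[["clothianidin_chronic"]]
    out <- list()
    if (!is.null(acute_clo) && !is.null(chronic_clo)) {
      n_sig_a <- sum(acute_clo$significant, na.rm = TRUE)
      n_sig_c <- sum(chronic_clo$significant, na.rm = TRUE)
      push("de_count_acute_clothianidin", n_sig_a,
           method = "nb_wald FDR 0.05")
      push("de_count_chronic_clothianidin", n_sig_c,
           method = "nb_wald FDR 0.05")
      if (n_sig_c > 0)
        push("de_count_ratio_acute_over_chronic", n_sig_a / n_sig_c,
             method = "count ratio")
      if (n_sig_a >= 20 && n_sig_c >= 20) {
        amp <- top_k_amplitude(acute_clo, chronic_clo, k = 20)
        out$amplitude <- amp
        push("amplitude_ratio_top20", amp$ratio, amp$df, amp$p, "welch_t")
      }
      if (n_sig_a > 0 && n_sig_c > 0) {
        prop <- proportion_large_changes(acute_clo, chronic_clo)
        out$proportion <- prop
        push("fourfold_proportion_chi2", prop$chi2, 1, prop$p, "chi2_2x2")
      }
    }
    # direction of the shared acute response
    sig_sets <- lapply(de$tables, function(t) t$gene_id[t$significant])
    acute_nm <- grep("_acute$", names(sig_sets), value = TRUE)
    if (length(acute_nm) >= 2) {
      shared <- Reduce(intersect, sig_sets[acute_nm])
      if (length(shared) >= 2) {
        lfc <- de$tables[[acute_nm[1]]]
        lfc <- lfc$log2fc[match(shared, lfc$gene_id)]
        up <- sum(lfc > 0); dn <- sum(lfc <= 0)
        gof <- chi2_gof(c(up, dn), c(0.5, 0.5))
        out$direction <- list(up = up, down = dn, gof = gof)
        push("shared_acute_up_count", up, method = "direction")
        push("shared_acute_direction_chi2", gof$chi2, gof$df, gof$p,
             "chi2_gof vs 50:50")
      }
    }
    # replicate-variance contrast; DE status = significant in any contrast
    # of the corresponding scheme
    if (any(samples$scheme == "acute") && any(samples$scheme == "chronic")) {
      chronic_nm <- grep("_chronic$", names(sig_sets), value = TRUE)
      flags <- rownames(de$kept) %in%
        unique(unlist(sig_sets[c(acute_nm, chronic_nm)]))
      if (any(flags) && !all(flags)) {
        vc <- variance_contrast(de$vst, samples, flags)
        out$variance <- vc
        push("variance_log_sd_coefficient", vc$coefficient, vc$df, vc$p,
             "paired log-SD contrast")
      }
    }
    df <- do.call(rbind, rows)
    add_file(write_table_fixed(df, file.path(outdir, "contrasts.csv"), ","))
    out$table <- df
    out
  })
  results$contrast <- contrast

  if (!is.null(config$subsample) || !is.null(config$confound)) {
    resample <- pipeline_stage("resample", verbose, {
      out <- list()
      if (!is.null(config$subsample) &&
          "clothianidin_chronic" %in% contrasts) {
        cfg <- config$subsample
        cfg$seed <- stage_seed(config$seed, 5L)
        bs <- balanced_subsample_de(
          dat$counts, samples, "clothianidin_chronic",
          acute_contrasts = grep("_acute$", contrasts, value = TRUE),
          settings = settings, config = cfg)
        out$balanced <- bs
        add_file(write_table_fixed(
          data.frame(iteration = seq_along(bs$de_counts),
                     de_count = bs$de_counts, subset = bs$subsets,
                     stringsAsFactors = FALSE),
          file.path(outdir, "subsample_counts.csv"), ","))
      }
      if (!is.null(config$confound) &&
          "clothianidin_chronic" %in% contrasts) {
        cfg <- config$confound
        cfg$seed <- stage_seed(config$seed, 6L)
        cc <- colony_confound_resample(dat$counts, samples,
                                       "clothianidin_chronic",
                                       settings = settings, config = cfg)
        out$confound <- cc
        add_file(write_table_fixed(
          data.frame(iteration = seq_along(cc$matched$de_counts),
                     matched = cc$matched$de_counts,
                     mismatched = cc$mismatched$de_counts),
          file.path(outdir, "confound_counts.csv"), ","))
        summ <- list(
          balanced = if (!is.null(out$balanced)) list(
            median = out$balanced$median,
            acute_p = lapply(out$balanced$acute, `[[`, "p")),
          confound = list(matched_median = cc$matched$median,
                          mismatched_median = cc$mismatched$median,
                          matched_skewness = cc$matched$skewness,
                          mismatched_skewness = cc$mismatched$skewness,
                          ks_D = cc$ks$D, ks_p = cc$ks$p))
        jsonlite::write_json(summ, file.path(outdir,
                                             "resampling_summary.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        add_file(file.path(outdir, "resampling_summary.json"))
      }
      out
    })
    results$resample <- resample
  }

  if (!is.null(dat$survival)) {
    surv <- pipeline_stage("survival", verbose, {
      rows <- lapply(contrasts, function(tr) {
        cx <- tryCatch(suppressWarnings(cox_ph(dat$survival, tr)),
                       error = function(e) NULL)
        if (is.null(cx)) return(NULL)
        data.frame(treatment = tr, beta = cx$beta, se = cx$se,
                   hazard_ratio = cx$hazard_ratio, p = cx$p,
                   score_chisq = cx$score_chisq, score_p = cx$score_p,
                   mortality = survival_proportion(dat$survival, tr, 14),
                   events = cx$events, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      df <- rbind(df, data.frame(
        treatment = "control", beta = NA, se = NA, hazard_ratio = NA,
        p = NA, score_chisq = NA, score_p = NA,
        mortality = survival_proportion(dat$survival, "control", 14),
        events = NA, stringsAsFactors = FALSE))
      add_file(write_table_fixed(df, file.path(outdir, "survival_results.csv"),
                                 ","))
      df
    })
    results$survival <- surv
  }

  if (!is.null(dat$intake)) {
    intake <- pipeline_stage("intake", verbose, {
      chronic_trs <- grep("_chronic$", contrasts, value = TRUE)
      acute_trs <- grep("_acute$", contrasts, value = TRUE)
      chronic_fit <- intake_ols(dat$intake, treatments = chronic_trs)
      acute_fit <- intake_ols(dat$intake, treatments = acute_trs,
                              acute_window = TRUE)
      cf <- rbind(cbind(model = "chronic", chronic_fit$coefficients),
                  cbind(model = "acute", acute_fit$coefficients))
      add_file(write_table_fixed(cf, file.path(outdir, "intake_ols.csv"),
                                 ","))
      # dose accounting over the exposure windows (chronic: after the two-
      # day adjustment; acute: final two days), per compound
      doses <- list()
      for (tr in contrasts) {
        scheme <- if (grepl("_acute$", tr)) "acute" else "chronic"
        conc <- if (scheme == "acute") 25 else 5
        sub <- dat$intake[dat$intake$treatment == tr, , drop = FALSE]
        sub <- if (scheme == "acute") sub[sub$day > 12, , drop = FALSE]
               else sub[sub$day > 2, , drop = FALSE]
        if (!nrow(sub)) next
        cd <- cumulative_dose(sub, conc)
        doses[[tr]] <- data.frame(treatment = tr,
                                  median_dose_ug_per_bee =
                                    cd$median_dose_ug_per_bee,
                                  stringsAsFactors = FALSE)
      }
      dose_df <- do.call(rbind, doses)
      add_file(write_table_fixed(dose_df, file.path(outdir, "doses.csv"),
                                 ","))
      list(chronic = chronic_fit, acute = acute_fit, doses = dose_df)
    })
    results$intake <- intake
  }

  manifest <- pipeline_stage("manifest", verbose, {
    files <- unique(files)
    md5 <- tools::md5sum(files)
    mf <- data.frame(file = basename(files), md5 = unname(md5),
                     stringsAsFactors = FALSE)
    write_table_fixed(mf, file.path(outdir, "manifest.csv"), ",")
    mf
  })

  out <- list(manifest = manifest, results = results, outdir = outdir,
              config = config)
  class(out) <- "pipeline_result"
  report <- pipeline_stage("report", verbose, write_report(out))
  out$report <- report
  invisible(out)
}

#' Write a human-readable run summary
#'
#' Plain-markdown tabulation of DE counts per contrast, overlap statistics,
#' scheme-contrast statistics, resampling summaries and survival results;
#' sections whose stage outputs are missing are marked absent.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param path output file (default `report.md` inside the run directory).
#' @return the report path, invisibly.
#' @export
write_report <- function(result, path = file.path(result$outdir,
                                                  "report.md")) {
  r <- result$results
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("# Exposure-scheme pipeline report")
  add("")
  add("## Differential expression (FDR ",
      fmt_num(result$config$settings$fdr_alpha), ")")
  if (!is.null(r$de)) {
    add("")
    add("| contrast | significant genes |")
    add("|---|---|")
    for (tr in names(r$de$tables))
      add("| ", tr, " | ",
          sum(r$de$tables[[tr]]$significant, na.rm = TRUE), " |")
  } else add("(absent)")
  add("")
  add("## Overlaps")
  if (!is.null(r$overlap) && length(r$overlap)) {
    for (scheme in names(r$overlap)) {
      t <- r$overlap[[scheme]]$test
      add("")
      add("- ", scheme, ": observed ", t$observed, ", expected ",
          fmt_num(t$expected), " (SE ", fmt_num(t$expected_se),
          "), fold ", fmt_num(t$fold_enrichment), ", p ",
          fmt_num(t$p_value))
    }
  } else add("(absent)")
  add("")
  add("## Scheme contrasts")
  if (!is.null(r$contrast$table)) {
    add("")
    add("| statistic | value | p |")
    add("|---|---|---|")
    for (i in seq_len(nrow(r$contrast$table)))
      add("| ", r$contrast$table$statistic[i], " | ",
          fmt_num(r$contrast$table$value[i]), " | ",
          fmt_num(r$contrast$table$p[i]), " |")
  } else add("(absent)")
  add("")
  add("## Resampling")
  if (!is.null(r$resample) && length(r$resample)) {
    if (!is.null(r$resample$balanced)) {
      add("")
      add("- balanced subsample median DE count: ",
          fmt_num(r$resample$balanced$median))
      for (nm in names(r$resample$balanced$acute))
        add("  - ", nm, ": observed ",
            r$resample$balanced$acute[[nm]]$de_count, ", permutation p ",
            fmt_num(r$resample$balanced$acute[[nm]]$p))
    }
    if (!is.null(r$resample$confound)) {
      cc <- r$resample$confound
      add("- colony confounding: matched median ",
          fmt_num(cc$matched$median), " vs mismatched ",
          fmt_num(cc$mismatched$median), "; KS D ", fmt_num(cc$ks$D),
          ", p ", fmt_num(cc$ks$p))
    }
  } else add("(absent)")
  add("")
  add("## Survival")
  if (!is.null(r$survival)) {
    add("")
    add("| treatment | hazard ratio | p | mortality |")
    add("|---|---|---|---|")
    for (i in seq_len(nrow(r$survival)))
      add("| ", r$survival$treatment[i], " | ",
          fmt_num(r$survival$hazard_ratio[i]), " | ",
          fmt_num(r$survival$p[i]), " | ",
          fmt_num(r$survival$mortality[i]), " |")
  } else add("(absent)")
  add("")
  add("## Intake and dose")
  if (!is.null(r$intake)) {
    add("")
    cf <- r$intake$chronic$coefficients
    ia <- grep("^day:treatment", cf$term)
    for (i in ia)
      add("- chronic interaction ", cf$term[i], ": ",
          fmt_num(cf$estimate[i]), " (SE ", fmt_num(cf$se[i]), ", p ",
          fmt_num(cf$p[i]), ")")
    if (!is.null(r$intake$doses))
      for (i in seq_len(nrow(r$intake$doses)))
        add("- median dose ", r$intake$doses$treatment[i], ": ",
            fmt_num(r$intake$doses$median_dose_ug_per_bee[i]),
            " ug per bee")
  } else add("(absent)")
  con <- file(path, open = "wb")
  writeLines(ln, con, sep = "\n")
  close(con)
  invisible(path)
}
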