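# Pipeline stages tying the modules together with reproducible artifacts.
# Each stage writes CSV/JSON outputs plus a JSON sidecar recording the
# seed, a config hash and the package version. A thin command-line
# wrapper over these functions ships in inst/cli/phenospline.R.

.config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251 + 1)) %% 1e9
}

.write_sidecar <- function(path, config, seed) {
  meta <- list(seed = seed, config_hash = .config_hash(config),
               package_version =
                 as.character(utils::packageVersion("phenospline")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE)
}

#' Simulate stage: write a synthetic cohort and its configuration
#'
#' @param config A [cohort_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written (`cohort.csv`, `config.yaml`).
#' @export
run_simulate <- function(config = cohort_config(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config)
  cohort_path <- file.path(outdir, "cohort.csv")
  utils::write.csv(cohort, cohort_path, row.names = FALSE)
  cfg <- config
  cfg$phenotype_params <- lapply(cfg$phenotype_params, as.list)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  .write_sidecar(cohort_path, config, config$seed)
  invisible(c(cohort = cohort_path,
              config = file.path(outdir, "config.yaml")))
}

#' Analyze stage: indices, descriptives, group statistics, regressions
#'
#' Appends metabolic indices and phenotype classification, writes the
#' descriptive summary, Kruskal-Wallis/Dunn tables across the true
#' phenotype labels, the subscale prevalence table, the Spearman matrix
#' of hormones and eating-behavior scores, and backward-eliminated HC3
#' OLS models for HOMA-IR and global EDE-Q.
#'
#' @param cohort Cohort data.frame (e.g. from [generate_cohort()] or read
#'   from the simulate stage's CSV).
#' @param outdir Output directory.
#' @param seed Seed recorded in the sidecars.
#' @return Invisibly, a list with the computed objects.
#' @export
run_analyze <- function(cohort, outdir = ".", seed = NA_integer_) {
  need <- c("oxytocin", "leptin", "edeq_global", "phenotype")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort is missing required column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- add_metabolic_indices(cohort)

  summ <- summarize_cohort(cohort)
  utils::write.csv(summ, file.path(outdir, "descriptives.csv"),
                   row.names = FALSE)

  gc_vars <- c("oxytocin", "leptin", "homa_ir", "hsi", "vai",
               "edeq_global")
  groups <- compare_groups(cohort, gc_vars, group_col = "phenotype")
  utils::write.csv(groups$tests, file.path(outdir, "kruskal_wallis.csv"),
                   row.names = FALSE)
  dunn_all <- do.call(rbind, lapply(names(groups$posthoc), function(v) {
    cbind(variable = v, groups$posthoc[[v]])
  }))
  utils::write.csv(dunn_all, file.path(outdir, "dunn_posthoc.csv"),
                   row.names = FALSE)

  prev <- prevalence_table(cohort, c(
    edeq_weight_concern = 4.0, edeq_shape_concern = 4.0,
    edeq_eating_concern = 4.0, edeq_restraint = 4.0,
    debq_emotional = 3.25, debq_external = 3.5, debq_restrained = 3.5,
    ebao_binge = 4.0, ebao_food_addiction = 4.0, ebao_hyperphagia = 4.0,
    ebao_night = 4.0, ebao_sweet = 4.0))
  utils::write.csv(prev, file.path(outdir, "prevalence.csv"),
                   row.names = FALSE)

  cor_vars <- c("oxytocin", "leptin", "bmi", "glucose", "homa_ir", "hsi",
                "vai", "edeq_global", .edeq_subscales)
  cors <- spearman_matrix(cohort, cor_vars)
  utils::write.csv(as.data.frame(cors$rho),
                   file.path(outdir, "spearman_rho.csv"))

  candidates <- c("oxytocin", "leptin", "bmi", "vai", "debq_emotional",
                  "debq_external", "debq_restrained",
                  "ebao_food_addiction", "ebao_night", "ebao_binge",
                  "ebao_sweet", "ebao_hyperphagia")
  model_a <- backward_eliminate(cohort, "homa_ir", candidates)
  model_b <- backward_eliminate(cohort, "edeq_global", candidates)
  for (nm in c("a", "b")) {
    m <- if (nm == "a") model_a else model_b
    utils::write.csv(m$fit$coefficients,
                     file.path(outdir, paste0("ols_model_", nm, ".csv")),
                     row.names = FALSE)
  }
  .write_sidecar(file.path(outdir, "descriptives.csv"),
                 list(vars = gc_vars, candidates = candidates), seed)
  invisible(list(summary = summ, groups = groups, prevalence = prev,
                 correlations = cors, model_a = model_a,
                 model_b = model_b, cohort = cohort))
}

#' Predict stage: nested CV, OOF metrics, cutoff mapping, decision curves
#'
#' Runs the leakage-free nested cross-validation for the oxytocin-only
#' and combined models, then computes OOF ROC/Brier, Youden operating
#' points, the paired bootstrap AUC difference, logistic recalibration,
#' the full-sample dose-response curve with the probability threshold
#' inverted to the oxytocin scale, and the decision curve.
#'
#' @param cohort Cohort data.frame.
#' @param outdir Output directory.
#' @param seed Seed for fold plan and bootstraps.
#' @param bootstrap_B Bootstrap replicates (>= 100).
#' @param outer_k,inner_k Fold counts.
#' @return Invisibly, a list with all computed objects.
#' @export
run_predict <- function(cohort, outdir = ".", seed = 1,
                        bootstrap_B = 2000, outer_k = 5, inner_k = 5) {
  if (bootstrap_B < 100) stop("bootstrap_B must be >= 100", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cohort <- add_metabolic_indices(cohort)
  y <- as.integer(cohort$edeq_global >= 2.5)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; prediction stage undefined",
         call. = FALSE)
  }
  plan <- make_fold_plan(y, outer_k = outer_k, inner_k = inner_k,
                         seed = seed)
  specs <- list(model_spec("oxytocin_only"), model_spec("combined"))
  oof <- collect_oof(cohort, y, specs, plan)
  pr <- oof$predictions
  utils::write.csv(pr, file.path(outdir, "oof_predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(outer = plan$outer, seed = plan$seed),
                       file.path(outdir, "fold_plan.json"))

  roc_a <- roc_result(pr$p_oxytocin_only, y, B = bootstrap_B, seed = seed)
  roc_b <- roc_result(pr$p_combined, y, B = bootstrap_B, seed = seed)
  yj_a <- youden_point(pr$p_oxytocin_only, y, B = bootstrap_B,
                       seed = seed)
  yj_b <- youden_point(pr$p_combined, y, B = bootstrap_B, seed = seed)
  dauc <- paired_delta_auc(pr$p_oxytocin_only, pr$p_combined, y,
                           B = bootstrap_B, seed = seed)
  cal_a <- calibration(pr$p_oxytocin_only, y)
  cal_b <- calibration(pr$p_combined, y)

  rcs_fit <- suppressWarnings(fit_rcs_logistic(y, cohort$oxytocin))
  curve <- dose_response(rcs_fit, data = list(y = y, x = cohort$oxytocin),
                         B = bootstrap_B, seed = seed)
  mapping <- map_threshold_to_biomarker(curve, yj_a$p_star)
  utils::write.csv(curve$curve, file.path(outdir, "dose_response.csv"),
                   row.names = FALSE)

  dca <- net_benefit(list(oxytocin_only = pr$p_oxytocin_only,
                          combined = pr$p_combined), y)
  utils::write.csv(dca$curve, file.path(outdir, "decision_curve.csv"),
                   row.names = FALSE)

  metrics <- list(
    prevalence = mean(y),
    oxytocin_only = list(auc = roc_a$auc, auc_ci = roc_a$auc_ci,
                         brier = roc_a$brier, p_star = yj_a$p_star,
                         sens = yj_a$sens, spec = yj_a$spec,
                         calibration_intercept = cal_a$intercept,
                         calibration_slope = cal_a$slope),
    combined = list(auc = roc_b$auc, auc_ci = roc_b$auc_ci,
                    brier = roc_b$brier, p_star = yj_b$p_star,
                    sens = yj_b$sens, spec = yj_b$spec,
                    calibration_intercept = cal_b$intercept,
                    calibration_slope = cal_b$slope),
    delta_auc = list(delta = dauc$delta, ci = dauc$ci, p = dauc$p),
    cutoff = list(p_star = mapping$p_star, value = mapping$cutoff,
                  ci = mapping$ci, found = mapping$found))
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_sidecar(file.path(outdir, "metrics.json"),
                 list(B = bootstrap_B, outer_k = outer_k,
                      inner_k = inner_k), seed)
  invisible(list(plan = plan, oof = oof, roc = list(oxytocin_only = roc_a,
                                                    combined = roc_b),
                 youden = list(oxytocin_only = yj_a, combined = yj_b),
                 delta_auc = dauc,
                 calibration = list(oxytocin_only = cal_a,
                                    combined = cal_b),
                 curve = curve, mapping = mapping, dca = dca,
                 metrics = metrics))
}
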