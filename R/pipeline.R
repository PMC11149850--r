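# End-to-end orchestration: simulate -> preprocess -> train extractor ->
# embed -> PCA -> fit feature-set models -> evaluate on test -> compare.
# Split discipline: the extractor, PCA and standardization see only the
# train split; the ridge penalty and extractor checkpoint selection see
# the tune split; the test split is touched only by evaluation. Every
# stage records the ids it consumed so leakage can be audited.

#' Default pipeline configuration
#'
#' Desk-scale study conditions: a 10,000-subject cohort split ~60/20/20 by
#' site region (about 6,000 train / 2,000 tune / 2,000 test).
#'
#' @param seed Global seed, fanned out to per-stage substreams.
#' @param n Cohort size.
#' @param feature_sets Registry names to fit.
#' @param comparisons List of `c(new, ref)` pairs.
#' @param extractor An [extractor_config()]; its seed is overridden by the
#'   run seed.
#' @param margin Non-inferiority margin (C percentage points).
#' @param n_perm Permutations for the non-inferiority test.
#' @param bootstrap_B Bootstrap iterations for CIs.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n = 10000L,
                       feature_sets = c("metadata", "office_refit_who", "dls",
                                        "dls_plus", "dls_plus_plus", "sbp140"),
                       comparisons = list(c("dls", "office_refit_who"),
                                          c("dls", "metadata")),
                       extractor = extractor_config(),
                       margin = 2.5, n_perm = 500L, bootstrap_B = 200L) {
  reg <- names(feature_set_registry())
  unknown <- setdiff(c(feature_sets, unlist(comparisons)), reg)
  if (length(unknown)) stop("unknown feature set(s): ", paste(unknown, collapse = ", "))
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 feature_sets = feature_sets, comparisons = comparisons,
                 extractor = extractor, margin = margin,
                 n_perm = as.integer(n_perm), bootstrap_B = as.integer(bootstrap_B)),
            class = "run_config")
}

# per-stage substreams derived from the run seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + match(stage, c("simulate", "extractor", "eval")) * 1009L) %% 2000000000L
}

#' Run the full pipeline
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return A `ppg_run` list: cohort, splits, features table, fitted
#'   models, per-model test metrics, comparison reports, leakage audit
#'   trail and timings.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating cohort (n = %d)", config$n)
  sp <- sim_params(n = config$n,
                   sites = default_sites(c(train = 0.6, tune = 0.2, test = 0.2)),
                   seed = .stage_seed(config$seed, "simulate"))
  cohort <- apply_inclusion_rules(simulate_cohort(sp))
  d <- cohort$data
  splits <- geographic_split(cohort)

  say("preprocessing %d waveforms", nrow(d))
  batch <- preprocess_waves(cohort$waves, ids = d$id)
  if (nrow(attr(batch, "excluded"))) {
    keep <- d$id %in% batch$ids
    d <- d[keep, , drop = FALSE]
    splits <- geographic_split(d)
  }
  sub_batch <- function(idx) {
    structure(list(values = batch$values[idx, , drop = FALSE],
                   lengths = batch$lengths[idx], ids = batch$ids[idx]),
              class = "padded_batch")
  }

  say("training extractor")
  exconf <- config$extractor
  exconf$seed <- .stage_seed(config$seed, "extractor")
  tr_b <- sub_batch(splits$train); tu_b <- sub_batch(splits$tune)
  extractor <- train_extractor(
    tr_b, d$time[splits$train], d$event[splits$train],
    tu_b, d$time[splits$tune], d$event[splits$tune],
    exconf, verbose = verbose)

  say("computing embeddings and PCA features")
  emb_all <- compute_embeddings(extractor, batch)$emb
  proj <- fit_pca(emb_all[splits$train, , drop = FALSE], k = 5L)
  scores <- project_pca(emb_all, proj)
  d <- cbind(d, as.data.frame(scores))

  trd <- d[splits$train, , drop = FALSE]
  tud <- d[splits$tune, , drop = FALSE]
  ted <- d[splits$test, , drop = FALSE]

  say("fitting feature-set models")
  models <- lapply(config$feature_sets, function(nm) fit_feature_set(nm, trd, tud))
  names(models) <- config$feature_sets

  say("evaluating on test split")
  preds <- lapply(models, predict_10yr_risk, newdata = ted)
  labels <- ten_year_label(ted$time, ted$event)
  eval_seed <- .stage_seed(config$seed, "eval")
  metrics <- lapply(names(models), function(nm) {
    p <- preds[[nm]]
    ok <- !is.na(p$p10)
    res <- list(
      name = nm, n = sum(ok),
      c_statistic = harrell_c(ted$time[ok], ted$event[ok], p$lp[ok], ci = TRUE,
                              B = config$bootstrap_B, seed = eval_seed)
    )
    if (models[[nm]]$type == "cox") {
      res$calibration <- tryCatch(calibration(p$p10[ok], ted$time[ok], ted$event[ok]),
                                  error = function(e) NULL)
    }
    res
  })
  names(metrics) <- names(models)

  say("model comparisons")
  run <- list(config = config, cohort_params = sp,
              data = d, splits = splits, extractor = extractor,
              pca = proj, models = models, predictions = preds,
              test_labels = labels, metrics = metrics,
              oracle_c = oracle_cstat(list(data = ted, params = sp) |>
                                        structure(class = "synthetic_cohort")),
              leakage = list(
                train_ids = d$id[splits$train], tune_ids = d$id[splits$tune],
                test_ids = d$id[splits$test],
                extractor_ids = tr_b$ids, extractor_select_ids = tu_b$ids,
                pca_ids = d$id[splits$train],
                scaler_ids = lapply(models, function(m) m$train_ids),
                lambda_ids = lapply(models, function(m) m$tune_ids)))
  run$comparisons <- lapply(config$comparisons, function(pair) {
    compare_models(run, pair[1], pair[2])
  })
  names(run$comparisons) <- vapply(config$comparisons,
                                   function(p) paste(p[1], "vs", p[2]), "")
  run$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(run) <- "ppg_run"
  run
}

#' Compare two fitted models on the shared test subjects
#'
#' Mirrors the headline comparison table: C with CI for both models, the
#' paired delta, non-inferiority and superiority permutation p-values,
#' category-free NRI components, calibration slope of the new model, and
#' threshold-matched operating points anchored to the SBP-140 rule.
#'
#' @param run A `ppg_run`.
#' @param new,ref Registry names of the two models.
#' @return A `model_comparison` list.
#' @export
compare_models <- function(run, new, ref) {
  pn <- run$predictions[[new]]; pr <- run$predictions[[ref]]
  if (is.null(pn) || is.null(pr)) stop("both models must be fitted in the run")
  ted <- run$data[run$splits$test, , drop = FALSE]
  ok <- !is.na(pn$p10) & !is.na(pr$p10)
  times <- ted$time[ok]; events <- ted$event[ok]
  labels <- ten_year_label(times, events)
  eval_seed <- .stage_seed(run$config$seed, "eval")

  pt <- permutation_noninferiority(pr$lp[ok], pn$lp[ok], times, events,
                                   margin = run$config$margin,
                                   n_perm = run$config$n_perm, seed = eval_seed)
  cf <- cfnri(pr$p10[ok], pn$p10[ok], labels)

  out <- list(new = new, ref = ref, n = sum(ok),
              c_new = .cstat(times, events, pn$lp[ok]),
              c_ref = .cstat(times, events, pr$lp[ok]),
              delta = pt$delta, noninferiority = pt, cfnri = cf)

  # operating points matched to the SBP-140 rule where SBP is available
  if ("sbp140" %in% names(run$models) && !all(is.na(ted$sbp))) {
    ref_pos <- sbp140_score(ted$sbp[ok]) == 1
    usable <- !is.na(ref_pos)
    if (any(usable & !is.na(labels))) {
      th_spec <- tryCatch(
        match_threshold(ref_pos[usable], labels[usable], pn$p10[ok][usable],
                        target = "specificity"), error = function(e) NA_real_)
      th_sens <- tryCatch(
        match_threshold(ref_pos[usable], labels[usable], pn$p10[ok][usable],
                        target = "sensitivity"), error = function(e) NA_real_)
      if (is.finite(th_spec)) {
        out$at_matched_specificity <- sens_spec(labels, pn$p10[ok], th_spec)
        out$threshold_matched_specificity <- th_spec
        out$nri_matched_specificity <-
          tryCatch(nri_at_threshold(pr$p10[ok], pn$p10[ok], labels, th_spec),
                   error = function(e) NULL)
      }
      if (is.finite(th_sens)) {
        out$at_matched_sensitivity <- sens_spec(labels, pn$p10[ok], th_sens)
        out$threshold_matched_sensitivity <- th_sens
      }
    }
  }
  cal <- tryCatch(calibration(pn$p10[ok], times, events), error = function(e) NULL)
  out$calibration_slope_new <- if (is.null(cal)) NA_real_ else cal$slope
  class(out) <- "model_comparison"
  out
}

#' Audit the run for train/tune/test leakage
#'
#' Asserts that no test-split subject influenced extractor weights, PCA,
#' feature standardization, or ridge-penalty selection, and that the
#' splits are disjoint.
#'
#' @param run A `ppg_run`.
#' @return Data frame of checks with a logical `ok` column.
#' @export
leakage_report <- function(run) {
  lk <- run$leakage
  checks <- list(
    splits_disjoint = length(intersect(lk$train_ids, lk$test_ids)) == 0 &&
      length(intersect(lk$tune_ids, lk$test_ids)) == 0 &&
      length(intersect(lk$train_ids, lk$tune_ids)) == 0,
    extractor_train_only = all(lk$extractor_ids %in% lk$train_ids),
    extractor_selection_tune_only = all(lk$extractor_select_ids %in% lk$tune_ids),
    pca_train_only = all(lk$pca_ids %in% lk$train_ids),
    scalers_train_only = all(vapply(lk$scaler_ids, function(ids)
      is.null(ids) || all(ids %in% lk$train_ids), logical(1))),
    lambda_tune_only = all(vapply(lk$lambda_ids, function(ids)
      is.null(ids) || all(ids %in% lk$tune_ids), logical(1)))
  )
  data.frame(check = names(checks), ok = unlist(checks), row.names = NULL)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (n = %d)\n", x$new, x$ref, x$n))
  cat(sprintf("  C: %.3f vs %.3f  (delta %.2f pp)\n", x$c_new, x$c_ref, x$delta))
  cat(sprintf("  non-inferiority p = %.4g (margin %.1f pp), superiority p = %.4g\n",
              x$noninferiority$p_noninferiority, x$noninferiority$margin,
              x$noninferiority$p_superiority))
  cat(sprintf("  cfNRI: overall %.2f%% (event %.2f%%, nonevent %.2f%%)\n",
              x$cfnri$overall, x$cfnri$event, x$cfnri$nonevent))
  if (!is.null(x$calibration_slope_new) && is.finite(x$calibration_slope_new))
    cat(sprintf("  calibration slope (%s): %.3f\n", x$new, x$calibration_slope_new))
  invisible(x)
}
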