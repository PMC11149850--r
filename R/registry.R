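# Named feature sets for the comparison models, standardization learned on
# the train split, age-interaction expansion for the deep-feature models,
# and absolute ten-year risk prediction.

MORPH_FEATURES <- c("pulse_rate", "reflection_index", "peak_to_peak_time",
                    "peak_position", "notch_position", "shoulder_position",
                    "stiffness_index", "notch_present")
DLS_FEATURES <- c(paste0("ppg", 1:5), "ppg_hr")

#' Registry of model feature sets
#'
#' `metadata` is age, sex and smoking status. `office_refit_who` adds BMI
#' and systolic blood pressure; `lab_refit_who` adds total cholesterol and
#' glucose. `metadata_morph` adds the engineered pulse-morphology features
#' (complete cases only). `dls` adds the five deep PPG features and PPG
#' heart rate; `dls_plus` / `dls_plus_plus` add BMI / BMI+SBP on top. The
#' deep-feature models carry age interactions with every non-age predictor;
#' `sbp140` is the binary screening rule, not a Cox fit.
#'
#' @return Named list of feature-set definitions (`features`,
#'   `interactions`, `binary`, `type`).
#' @export
feature_set_registry <- function() {
  meta <- c("age", "sex", "smoking")
  mk <- function(features, interactions = FALSE, type = "cox") {
    list(features = features,
         interactions = if (interactions) setdiff(features, "age") else character(0),
         binary = c("sex", "smoking", "notch_present"),
         type = type)
  }
  list(
    metadata = mk(meta),
    office_refit_who = mk(c(meta, "bmi", "sbp")),
    lab_refit_who = mk(c(meta, "tchol", "glucose")),
    metadata_morph = mk(c(meta, MORPH_FEATURES)),
    dls = mk(c(meta, DLS_FEATURES), interactions = TRUE),
    dls_plus = mk(c(meta, DLS_FEATURES, "bmi"), interactions = TRUE),
    dls_plus_plus = mk(c(meta, DLS_FEATURES, "bmi", "sbp"), interactions = TRUE),
    sbp140 = list(features = "sbp", interactions = character(0),
                  binary = character(0), type = "rule")
  )
}

# Resolve feature columns in a cohort table; hidden simulator columns
# (prefixed "_latent") are never legal model inputs.
resolve_features <- function(data, features) {
  if (any(startsWith(features, "_latent"))) {
    stop("latent simulator columns cannot be used as model features")
  }
  missing <- setdiff(features, names(data))
  if (length(missing)) stop("feature set not resolvable; missing columns: ",
                            paste(missing, collapse = ", "))
  data[, features, drop = FALSE]
}

# Standardization stats on the train split (binary features pass through).
learn_scaler <- function(train_df, features, binary) {
  stats_ <- lapply(features, function(f) {
    x <- train_df[[f]]
    if (f %in% binary) return(list(mean = 0, sd = 1))
    m <- mean(x); s <- stats::sd(x)
    # a zero-variance feature standardizes to a constant-zero column and is
    # dropped downstream rather than failing the whole fit
    if (!is.finite(s) || s <= 0) s <- 1
    list(mean = m, sd = s)
  })
  names(stats_) <- features
  stats_
}

# Build the standardized design matrix incl. age-interaction columns.
build_design <- function(df, spec) {
  X <- sapply(spec$features, function(f) {
    (as.numeric(df[[f]]) - spec$scaler[[f]]$mean) / spec$scaler[[f]]$sd
  })
  X <- matrix(X, nrow = nrow(df), dimnames = list(NULL, spec$features))
  if (length(spec$interactions)) {
    Z <- sapply(spec$interactions, function(f) X[, "age"] * X[, f])
    Z <- matrix(Z, nrow = nrow(df),
                dimnames = list(NULL, paste0("age:", spec$interactions)))
    X <- cbind(X, Z)
  }
  if (!is.null(spec$keep)) X <- X[, spec$keep, drop = FALSE]
  X
}

#' Fit one registry feature set end to end
#'
#' Resolves the features, learns standardization on the train split, tunes
#' the ridge penalty on the tune split, refits on train at the selected
#' penalty, and attaches the Breslow baseline cumulative hazard. Rows with
#' missing features are dropped (complete-case fitting per feature set).
#'
#' @param name Registry name (see [feature_set_registry()]).
#' @param train_df,tune_df Cohort tables with `time` (days) and `event`.
#' @param lambda_grid Ridge penalty grid.
#' @param registry Optional registry override.
#' @return A `ppg_cox_model`: coefficients, scaler, penalty, baseline
#'   hazard, split bookkeeping.
#' @export
fit_feature_set <- function(name, train_df, tune_df,
                            lambda_grid = c(0.01, 0.1, 1, 10, 100),
                            registry = feature_set_registry()) {
  def <- registry[[name]]
  if (is.null(def)) stop("unknown feature set: ", name)
  if (def$type == "rule") {
    return(structure(list(name = name, type = "rule"), class = "ppg_cox_model"))
  }
  cc_tr <- stats::complete.cases(resolve_features(train_df, def$features))
  cc_tu <- stats::complete.cases(resolve_features(tune_df, def$features))
  tr <- train_df[cc_tr, , drop = FALSE]
  tu <- tune_df[cc_tu, , drop = FALSE]
  spec <- list(features = def$features, interactions = def$interactions,
               scaler = learn_scaler(tr, def$features, def$binary))
  Xtr <- build_design(tr, spec)
  # constant columns carry no information and break the fit (e.g. a
  # landmark-presence flag that is uniform in a cohort)
  keep <- apply(Xtr, 2, stats::sd) > 0
  spec$keep <- colnames(Xtr)[keep]
  Xtr <- Xtr[, keep, drop = FALSE]
  Xtu <- build_design(tu, spec)
  sel <- tune_ridge(Xtr, tr$time, tr$event, Xtu, tu$time, tu$event, lambda_grid)
  fit <- fit_cox_ridge(Xtr, tr$time, tr$event, sel$lambda)
  lp_tr <- as.vector(Xtr %*% fit$beta)
  base <- breslow_baseline(lp_tr, tr$time, tr$event)
  structure(list(
    name = name, type = "cox", spec = spec,
    beta = stats::setNames(fit$beta, colnames(Xtr)),
    lambda = sel$lambda, lambda_grid = lambda_grid,
    tune_loglik = sel$tune_loglik, baseline = base,
    train_ids = tr$id, tune_ids = tu$id,
    n_train = nrow(tr), n_events_train = sum(tr$event)
  ), class = "ppg_cox_model")
}

#' Predict ten-year event risk
#'
#' \eqn{p_{10} = 1 - \exp(-H_0(10\,\mathrm{y}) e^{lp})}, strictly
#' increasing in the linear predictor. For the `sbp140` rule the "risk" is
#' the 0/1 flag itself.
#'
#' @param model A `ppg_cox_model`.
#' @param newdata Cohort table.
#' @param horizon_days Risk horizon (default ten years).
#' @return Data frame: `id`, `lp`, `p10` (`NA` where features are missing).
#' @export
predict_10yr_risk <- function(model, newdata, horizon_days = TEN_YEARS_DAYS) {
  if (model$type == "rule") {
    flag <- sbp140_score(newdata$sbp)
    return(data.frame(id = newdata$id, lp = flag, p10 = flag))
  }
  cc <- stats::complete.cases(resolve_features(newdata, model$spec$features))
  lp <- rep(NA_real_, nrow(newdata)); p10 <- rep(NA_real_, nrow(newdata))
  if (any(cc)) {
    X <- build_design(newdata[cc, , drop = FALSE], model$spec)
    lp[cc] <- as.vector(X %*% model$beta)
    H10 <- model$baseline$fun(horizon_days)
    p10[cc] <- 1 - exp(-H10 * exp(lp[cc]))
  }
  data.frame(id = newdata$id, lp = lp, p10 = p10)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `ppg_cox_model`.
#' @param path Output path.
#' @export
write_cox_model_json <- function(model, path) {
  obj <- list(name = model$name, type = model$type)
  if (model$type == "cox") {
    obj$beta <- as.list(model$beta)
    obj$lambda <- model$lambda
    obj$scaler <- model$spec$scaler
    obj$interactions <- model$spec$interactions
    obj$baseline <- list(time = model$baseline$time, hazard = model$baseline$hazard)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
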