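#' Apply the published VAT bias correction
#'
#' Corrects the systematic underestimation of threshold-derived visceral
#' adipose tissue area with the linear model
#' `VAT_corrected = 7.224 + 1.112 * VAT_otsu + 7.583 * I_obesity` (cm²),
#' where `I_obesity` is 1 for obese patients and 0 otherwise. The
#' coefficients are cohort- and protocol-specific; refit with [fit_wls()]
#' for other acquisition settings.
#'
#' @param vat_otsu_cm2 Automated VAT area(s), cm², >= 0.
#' @param obesity Obesity indicator(s), 0 or 1.
#' @return Corrected VAT area(s) in cm².
#' @export
apply_vat_correction <- function(vat_otsu_cm2, obesity) {
  check_correction_inputs(vat_otsu_cm2, obesity)
  7.224 + 1.112 * vat_otsu_cm2 + 7.583 * obesity
}

#' Apply the published SAT bias correction
#'
#' Linear correction of automated subcutaneous adipose tissue area:
#' `SAT_corrected = 0.67 + 1.037 * SAT_otsu + 3.337 * I_adult` (cm²),
#' where `I_adult` is 1 for adults and 0 for children.
#'
#' @param sat_otsu_cm2 Automated SAT area(s), cm², >= 0.
#' @param adult Adult-age indicator(s), 0 or 1.
#' @return Corrected SAT area(s) in cm².
#' @export
apply_sat_correction <- function(sat_otsu_cm2, adult) {
  check_correction_inputs(sat_otsu_cm2, adult)
  0.67 + 1.037 * sat_otsu_cm2 + 3.337 * adult
}

check_correction_inputs <- function(area, indicator) {
  if (any(area < 0)) stop("area must be non-negative", call. = FALSE)
  if (!all(indicator %in% c(0, 1))) {
    stop("indicator must be 0 or 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Inverse-frequency Sex x Age weights
#'
#' Per-record weights equal to the reciprocal of the record's
#' Sex x Age-category cell count, so that each of the four demographic
#' cells contributes equally to a weighted fit regardless of cohort
#' imbalance. The weighted count of every cell sums to 1.
#'
#' @param records Data.frame with `sex` and `age_category` columns.
#' @return Numeric weight vector, one per record.
#' @export
inverse_frequency_weights <- function(records) {
  stopifnot(all(c("sex", "age_category") %in% names(records)))
  cell <- interaction(records$sex, records$age_category, drop = TRUE)
  counts <- table(cell)
  as.numeric(1 / counts[as.character(cell)])
}

# Build the design matrix (without intercept column) for a set of term
# names. A term is either a column of `records` (numeric, or a
# reference-coded factor: male/adult/obesity dummies) or an interaction
# "a:b" (product of the two columns). With `center`, binary columns are
# mean-centered before products are formed.
build_design <- function(records, terms, center = FALSE) {
  base_col <- function(nm) {
    v <- switch(nm,
                sex = as.numeric(records$sex == "male"),
                age_category = as.numeric(records$age_category == "adult"),
                {
                  if (!nm %in% names(records)) {
                    stop("unknown model term '", nm, "'", call. = FALSE)
                  }
                  as.numeric(records[[nm]])
                })
    v
  }
  centered <- function(nm) {
    v <- base_col(nm)
    if (center && all(v %in% c(0, 1))) v - mean(v) else v
  }
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1L) base_col(tm) else Reduce(`*`, lapply(parts, centered))
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Fit a weighted least-squares calibration model
#'
#' Regresses a manual-reference area on the supplied regressors by
#' weighted least squares, minimizing `sum w_i (y_i - x_i' beta)^2`.
#' Reference coding follows the cohort convention: female, child and
#' normal weight are the reference levels (so `sex` enters as a male
#' dummy and `age_category` as an adult dummy). Reports normal-theory
#' 95% confidence intervals, the weighted R², the residual standard
#' deviation, and Bland-Altman limits of agreement of the fitted
#' predictions against the observed responses.
#'
#' @param records Cohort data.frame (see [generate_cohort()] for the
#'   column convention).
#' @param response Name of the response column (e.g. `"vat_manual_cm2"`).
#' @param regressors Character vector of term names; an intercept is
#'   always included. Interactions are written `"a:b"`.
#' @param weighting `"inverse_sex_age_frequency"` (default) or `"none"`.
#' @param weights Optional explicit positive weights overriding
#'   `weighting`.
#' @return An object of class `calibration_model`.
#' @export
fit_wls <- function(records, response, regressors,
                    weighting = c("inverse_sex_age_frequency", "none"),
                    weights = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(response %in% names(records))
  n <- nrow(records)
  if (n <= length(regressors) + 1L) {
    stop("need more records (", n, ") than model terms (",
         length(regressors) + 1L, ")", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- if (weighting == "inverse_sex_age_frequency") {
      inverse_frequency_weights(records)
    } else {
      rep(1, n)
    }
  } else {
    stopifnot(length(weights) == n, all(weights > 0))
    weighting <- "user"
  }
  X <- build_design(records, regressors)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- c("(Intercept)", colnames(X))[-qrX$pivot[seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear terms: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(.y = records[[response]], X, check.names = FALSE)
  fml <- stats::as.formula(paste0(".y ~ `", paste(regressors, collapse = "` + `"), "`"))
  fit <- lm(fml, data = dat, weights = weights)
  sm <- summary(fit)
  co <- coef(fit)
  names(co) <- c("(Intercept)", regressors)
  ci <- confint(fit, level = 0.95)
  rownames(ci) <- names(co)
  pred <- as.vector(fit$fitted.values)
  ba <- bland_altman(pred, records[[response]])
  structure(list(response = response,
                 terms = co,
                 conf_int = ci,
                 weighting = weighting,
                 weights = weights,
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 loa_lower_cm2 = ba$loa_lower,
                 loa_upper_cm2 = ba$loa_upper,
                 mean_diff_cm2 = ba$mean_diff,
                 n = n,
                 fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>", x$response, sprintf("(n = %d, weighting = %s)\n",
                                                 x$n, x$weighting))
  print(round(x$terms, 4))
  cat(sprintf("  R² = %.4f, residual SD = %.3f cm², LoA [%.3f, %.3f] cm²\n",
              x$r_squared, x$residual_sd, x$loa_lower_cm2, x$loa_upper_cm2))
  invisible(x)
}

#' Predict from a calibration model
#'
#' @param object A `calibration_model`.
#' @param newdata Data.frame with the model's regressor columns.
#' @param ... Unused.
#' @return Predicted response values.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  terms <- names(object$terms)[-1]
  X <- build_design(newdata, terms)
  as.vector(object$terms[1] + X %*% object$terms[-1])
}

#' Exhaustive subset model selection
#'
#' Enumerates every subset of the optional candidate terms (the intercept
#' and the area predictor are always retained), fits each candidate model
#' by weighted least squares, and picks the subset minimizing an
#' information criterion, ties broken towards fewer terms. The default
#' criterion is BIC: its heavier complexity penalty is consistent
#' (asymptotically selects exactly the active terms), which matches the
#' role of the correction models — a small, interpretable set of
#' predictors — better than AIC's fixed penalty of 2. Both the winning
#' fit and the full-model fit are returned.
#'
#' @param records Cohort data.frame.
#' @param response Response column name.
#' @param always_keep Terms present in every candidate (default: the area
#'   predictor inferred from `response`).
#' @param candidates Optional character vector of candidate terms;
#'   defaults to the dummy-coded sex/age/obesity main effects and their
#'   interactions with the area predictor.
#' @param criterion `"bic"` (default) or `"aic"`.
#' @param weighting Passed to [fit_wls()].
#' @return A list with `terms` (selected optional terms), `model` (the
#'   refitted winner), `full_model`, and `table` (criterion per subset).
#' @export
select_model <- function(records, response, always_keep = NULL,
                         candidates = NULL, criterion = c("bic", "aic"),
                         weighting = c("inverse_sex_age_frequency", "none")) {
  weighting <- match.arg(weighting)
  criterion <- match.arg(criterion)
  score_fn <- if (criterion == "bic") stats::BIC else AIC
  if (is.null(always_keep)) {
    always_keep <- if (grepl("^vat", response)) "vat_otsu_cm2" else "sat_otsu_cm2"
  }
  if (is.null(candidates)) {
    area <- always_keep[1]
    mains <- c("sex", "age_category", if ("obesity" %in% names(records)) "obesity")
    candidates <- c(mains, paste(mains, area, sep = ":"))
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(candidates)))
  scores <- vapply(seq_len(nrow(subsets)), function(i) {
    tms <- c(always_keep, candidates[unlist(subsets[i, ])])
    fit <- tryCatch(fit_wls(records, response, tms, weighting = weighting),
                    error = function(e) NULL)
    if (is.null(fit)) Inf else score_fn(fit$fit)
  }, numeric(1))
  sizes <- rowSums(subsets)
  best <- order(scores, sizes)[1]
  chosen <- candidates[unlist(subsets[best, ])]
  list(terms = chosen,
       model = fit_wls(records, response, c(always_keep, chosen),
                       weighting = weighting),
       full_model = fit_wls(records, response, c(always_keep, candidates),
                            weighting = weighting),
       table = data.frame(subset = apply(subsets, 1, function(r)
         paste(candidates[unlist(r)], collapse = "+")),
         n_terms = sizes, score = scores, criterion = criterion))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R²_j)` where `R²_j` is from regressing predictor `j`
#' on the remaining predictors (with intercept). With
#' `center_interactions`, binary dummy columns are mean-centered before
#' interaction products are formed, the standard remedy for the
#' structural collinearity of raw products. Perfectly collinear terms
#' report `Inf` rather than erroring.
#'
#' @param records Cohort data.frame.
#' @param terms Character vector of at least two term names
#'   (interactions as `"a:b"`).
#' @param center_interactions Mean-center binary columns inside products.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(records, terms, center_interactions = TRUE) {
  stopifnot(length(terms) >= 2)
  X <- build_design(records, terms, center = center_interactions)
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(terms)
}

#' Bland-Altman limits of agreement
#'
#' Mean difference between two paired measurement methods and the limits
#' `mean ± multiplier * SD` of the differences (SD with the `n - 1`
#' denominator); with the default multiplier 1.96 the limits bracket
#' ~95% of normally distributed differences.
#'
#' @param predicted,reference Paired numeric vectors of equal length >= 2.
#' @param multiplier Half-width multiplier (default 1.96).
#' @return A list `mean_diff`, `loa_lower`, `loa_upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(predicted, reference, multiplier = 1.96) {
  stopifnot(length(predicted) == length(reference))
  if (length(predicted) < 2) stop("need at least 2 paired values", call. = FALSE)
  d <- predicted - reference
  md <- mean(d); s <- sd(d)
  list(mean_diff = md, loa_lower = md - multiplier * s,
       loa_upper = md + multiplier * s, sd_diff = s, n = length(d))
}

#' BCa bootstrap confidence interval
#'
#' Nonparametric bootstrap of a statistic with the bias-corrected and
#' accelerated (BCa) interval: the bias correction `z0` comes from the
#' fraction of bootstrap replicates below the observed statistic and the
#' acceleration `a` from the jackknife skewness. Deterministic given
#' `seed`. A degenerate (zero-variance) statistic yields a zero-width
#' interval with a warning.
#'
#' @param data Vector or data.frame; resampling is over elements/rows.
#' @param statistic Function of a resample returning one number.
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer RNG seed.
#' @return A list `lower`, `upper`, `estimate`, `z0`, `acceleration`.
#' @export
bootstrap_bca <- function(data, statistic, n_resamples = 10000L,
                          conf = 0.95, seed = 1L) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 10) stop("need at least 10 observations to bootstrap", call. = FALSE)
  pick <- if (is.data.frame(data)) {
    function(i) data[i, , drop = FALSE]
  } else {
    function(i) data[i]
  }
  obs <- statistic(data)
  boots <- with_seed(seed, {
    vapply(seq_len(n_resamples),
           function(b) statistic(pick(sample.int(n, n, replace = TRUE))),
           numeric(1))
  })
  if (sd(boots) == 0) {
    warning("degenerate statistic: bootstrap distribution has zero variance")
    return(list(lower = obs, upper = obs, estimate = obs, z0 = 0,
                acceleration = 0))
  }
  z0 <- qnorm(mean(boots < obs) + 0.5 * mean(boots == obs))
  jack <- vapply(seq_len(n), function(i) statistic(pick(-i)), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - conf) / 2
  adj <- function(q) {
    z <- z0 + qnorm(q)
    pnorm(z0 + z / (1 - a * z))
  }
  qs <- quantile(boots, c(adj(alpha), adj(1 - alpha)), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], estimate = obs, z0 = z0, acceleration = a)
}

#' Cross-validate a calibration model
#'
#' Internal validation by leave-one-out or repeated k-fold
#' cross-validation. Each training fold refits the model and recomputes
#' the inverse-frequency Sex x Age weights from the training records
#' only; held-out predictions are pooled before scoring. Folds whose
#' training design is rank deficient are skipped with a warning and
#' counted.
#'
#' @param records Cohort data.frame.
#' @param response Response column name.
#' @param regressors Model terms as in [fit_wls()].
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Folds for `"kfold"` (default 10).
#' @param repeats Repeats for `"kfold"` (default 100).
#' @param weighting Passed to [fit_wls()].
#' @param seed Integer RNG seed for fold assignment.
#' @return An object of class `cv_result`: `scheme`, `r_squared`,
#'   `rmse_cm2`, `mae_cm2`, `mean_bias_cm2`, `n_folds_skipped`, `seed`.
#' @export
cross_validate <- function(records, response, regressors,
                           scheme = c("loocv", "kfold"), k = 10L,
                           repeats = 100L,
                           weighting = c("inverse_sex_age_frequency", "none"),
                           seed = 1L) {
  scheme <- match.arg(scheme)
  weighting <- match.arg(weighting)
  n <- nrow(records)
  y <- records[[response]]
  skipped <- 0L

  predict_fold <- function(train_idx, test_idx) {
    fit <- tryCatch(fit_wls(records[train_idx, , drop = FALSE], response,
                            regressors, weighting = weighting),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    predict(fit, records[test_idx, , drop = FALSE])
  }

  if (scheme == "loocv") {
    preds <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      p <- predict_fold(setdiff(seq_len(n), i), i)
      if (is.null(p)) skipped <- skipped + 1L else preds[i] <- p
    }
    pooled_pred <- preds
    pooled_obs <- y
  } else {
    if (n < k) stop("n (", n, ") must be at least k (", k, ")", call. = FALSE)
    folds_all <- with_seed(seed, {
      lapply(seq_len(repeats), function(r) sample(rep_len(seq_len(k), n)))
    })
    pooled_pred <- numeric(0)
    pooled_obs <- numeric(0)
    for (r in seq_len(repeats)) {
      fold <- folds_all[[r]]
      preds <- rep(NA_real_, n)
      for (f in seq_len(k)) {
        test_idx <- which(fold == f)
        p <- predict_fold(which(fold != f), test_idx)
        if (is.null(p)) skipped <- skipped + 1L else preds[test_idx] <- p
      }
      keep <- !is.na(preds)
      pooled_pred <- c(pooled_pred, preds[keep])
      pooled_obs <- c(pooled_obs, y[keep])
    }
  }
  if (skipped > 0) {
    warning(skipped, " fold(s) skipped due to rank-deficient training design")
  }
  ok <- complete.cases(pooled_pred, pooled_obs)
  err <- pooled_pred[ok] - pooled_obs[ok]
  ss_res <- sum(err^2)
  ss_tot <- sum((pooled_obs[ok] - mean(pooled_obs[ok]))^2)
  structure(list(scheme = if (scheme == "kfold")
    sprintf("repeated_%dfold_x%d", k, repeats) else "loocv",
    r_squared = 1 - ss_res / ss_tot,
    rmse_cm2 = sqrt(mean(err^2)),
    mae_cm2 = mean(abs(err)),
    mean_bias_cm2 = mean(err),
    n_folds_skipped = skipped,
    seed = as.integer(seed)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$scheme, "\n")
  cat(sprintf("  R² = %.4f, RMSE = %.3f cm², MAE = %.3f cm², bias = %.3f cm²\n",
              x$r_squared, x$rmse_cm2, x$mae_cm2, x$mean_bias_cm2))
  if (x$n_folds_skipped > 0) cat("  skipped folds:", x$n_folds_skipped, "\n")
  invisible(x)
}

#' Read / write a calibration model as JSON
#'
#' Serializes the named coefficients, weighting scheme and fit summary of
#' a calibration model to a flat JSON file. The package ships two model
#' files encoding the published corrections, `vat_eq1.json` and
#' `sat_eq2.json`, under `inst/extdata/`.
#'
#' @param path JSON file path.
#' @return For `read_calibration_model`, a list with `response`, `terms`
#'   (named coefficients), and `weighting`; prediction works via
#'   [predict_from_terms()].
#' @export
read_calibration_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(!is.null(m$response), !is.null(m$terms))
  m$terms <- unlist(m$terms)
  m
}

#' @rdname read_calibration_model
#' @param model A `calibration_model` or a list with `response`/`terms`.
#' @export
write_calibration_model <- function(model, path) {
  out <- list(response = model$response,
              terms = as.list(model$terms),
              weighting = model$weighting,
              r_squared = model$r_squared,
              loa_lower_cm2 = model$loa_lower_cm2,
              loa_upper_cm2 = model$loa_upper_cm2,
              n = model$n)
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Predict from serialized model terms
#'
#' @param model List with named `terms` (first element the intercept).
#' @param newdata Data.frame with the regressor columns.
#' @return Predicted values.
#' @export
predict_from_terms <- function(model, newdata) {
  terms <- names(model$terms)
  stopifnot(terms[1] == "(Intercept)")
  X <- build_design(newdata, terms[-1])
  as.vector(model$terms[1] + X %*% model$terms[-1])
}
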