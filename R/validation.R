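#' QSAR validation statistics and the model-acceptance rule set
#'
#' Implements the external-validation statistics used to accept or reject
#' a 3D-QSAR model: the squared Pearson correlation r2 of predicted vs
#' observed, the zero-intercept coefficients of determination r0^2 (and its
#' role-swapped twin r'0^2), the through-origin regression slopes k and k',
#' rm^2 = r2 (1 - sqrt|r2 - r0^2|), RMSE, the F statistic of the regression
#' with (m, n - m - 1) degrees of freedom, leave-one-out model stability,
#' and the acceptance conjunction
#' q2 > 0.5, r2 > 0.6, (r2 - r0^2)/r2 < 0.1, (r2 - r'0^2)/r2 < 0.1,
#' 0.85 <= k <= 1.15, rm^2 > 0.5.
#'
#' The literature's printed formula for k (sum(pred*obs)/sum(pred)) fails
#' the identity case pred == obs and is inconsistent with the 0.85-1.15
#' acceptance band; the standard through-origin slope
#' k = sum(pred*obs)/sum(pred^2) is used by default, with the printed form
#' available behind `legacy_k = TRUE` for auditability.
#'
#' @name qsar-validation
NULL

#' Regression validation statistics between predictions and observations
#'
#' @param pred,obs numeric vectors of equal length >= 3; `obs` must be
#'   non-constant.
#' @param legacy_k use the literature's printed k denominator (sum(pred))
#'   instead of the through-origin slope denominator (sum(pred^2)).
#' @return list with r2, r0_2, r0p_2, k, k_prime, rm_2, pearson_r, rmse, sd
#'   (residual standard deviation) and n.
#' @export
regression_validation_stats <- function(pred, obs, legacy_k = FALSE) {
  if (length(pred) != length(obs)) stop("pred and obs differ in length")
  if (length(obs) < 3) stop("need at least 3 points")
  if (stats::sd(obs) < 1e-12) stop("constant observations")
  if (stats::sd(pred) < 1e-12) stop("constant predictions: Pearson undefined")
  r <- stats::cor(pred, obs)
  r2 <- r^2
  r0_2 <- 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
  r0p_2 <- 1 - sum((obs - pred)^2) / sum((pred - mean(pred))^2)
  k <- if (legacy_k) sum(pred * obs) / sum(pred) else
    sum(pred * obs) / sum(pred^2)
  k_prime <- if (legacy_k) sum(pred * obs) / sum(obs) else
    sum(pred * obs) / sum(obs^2)
  rm_2 <- r2 * (1 - sqrt(abs(r2 - r0_2)))
  rmse <- sqrt(mean((pred - obs)^2))
  list(r2 = r2, r0_2 = r0_2, r0p_2 = r0p_2, k = k, k_prime = k_prime,
       rm_2 = rm_2, pearson_r = r, rmse = rmse,
       sd = stats::sd(obs - pred), n = length(obs))
}

#' F statistic of a regression model
#'
#' The ratio of model variance to residual activity variance:
#' `F = (r2/m) / ((1 - r2)/(n - m - 1))` with degrees of freedom m (PLS
#' factors) and n - m - 1 (ligand count minus factors minus one); the
#' p-value is the upper-tail F probability.
#'
#' @param r2 coefficient of determination in [0, 1).
#' @param m number of PLS factors (model degrees of freedom).
#' @param n number of ligands.
#' @return list with `F` and `p`.
#' @export
f_statistic <- function(r2, m, n) {
  if (r2 < 0 || r2 > 1) stop("r2 out of [0, 1]")
  if (n <= m + 1) stop("invalid degrees of freedom: need n > m + 1")
  if (r2 == 1) return(list(F = Inf, p = 0))
  df2 <- n - m - 1
  Fv <- (r2 / m) / ((1 - r2) / df2)
  list(F = Fv, p = stats::pf(Fv, m, df2, lower.tail = FALSE))
}

#' External q2 on a held-out test set
#'
#' The zero-intercept coefficient of determination applied to test-set
#' predictions against observations, with the mean taken over the test-set
#' observations.
#'
#' @param pred,obs test-set predictions and observations (non-empty).
#' @return q2 value.
#' @export
external_q2 <- function(pred, obs) {
  if (length(obs) == 0) stop("empty test set")
  if (length(pred) != length(obs)) stop("pred and obs differ in length")
  1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
}

#' Leave-one-out stability of a model-fitting procedure
#'
#' For each training compound the model is refitted without it and the
#' left-out compound predicted; stability is the r2 between the LOO
#' prediction vector and the full-model predictions on the same compounds
#' (maximum 1).
#'
#' @param X,y training design matrix and activity vector.
#' @param n_factors PLS factor count (held fixed across refits).
#' @param t_cutoff jackknife t filter cutoff passed to each refit; by
#'   default the filter is skipped during stability refits (it is part of
#'   the full fit, and refiltering per fold is both slow and a different
#'   question than coefficient stability).
#' @param apply_t_filter re-apply the t filter inside each refit.
#' @return stability in [0, 1] (clamped below at 0).
#' @export
loo_stability <- function(X, y, n_factors = 1L, t_cutoff = 2.0,
                          apply_t_filter = FALSE) {
  n <- length(y)
  if (n < 5) stop("need >= 5 training compounds for LOO stability")
  keep <- which(apply(X, 2, function(col) length(unique(col)) > 1))
  Xk <- X[, keep, drop = FALSE]
  full <- pls1_fit(Xk, y, n_factors)
  full_pred <- pls1_predict(full, Xk)
  loo_pred <- numeric(n)
  failures <- character(0)
  for (i in seq_len(n)) {
    f <- tryCatch(pls1_fit(Xk[-i, , drop = FALSE], y[-i], n_factors),
                  error = function(e) NULL)
    if (is.null(f)) { failures <- c(failures, as.character(i)); next }
    loo_pred[i] <- pls1_predict(f, Xk[i, , drop = FALSE])
  }
  if (length(failures) > 0) {
    stop("degenerate LOO refits leaving out compound(s): ",
         paste(failures, collapse = ", "))
  }
  if (stats::sd(loo_pred) < 1e-12 || stats::sd(full_pred) < 1e-12) return(0)
  max(0, min(1, stats::cor(loo_pred, full_pred)^2))
}

#' Assemble a full validation report for a fitted model
#'
#' @param model a `qp_qsar_model`.
#' @param test_mols held-out molecules with observed pIC50 (external q2 and
#'   the prediction statistics are computed on them).
#' @param X_train training design matrix (for LOO stability); taken from
#'   scratch via the model metadata when NULL.
#' @param legacy_k see [regression_validation_stats()].
#' @return list of class `qp_validation_report`.
#' @export
validation_report <- function(model, test_mols, X_train = NULL,
                              legacy_k = FALSE) {
  pred_test <- vapply(test_mols, function(m) predict_molecule(model, m),
                      numeric(1))
  obs_test <- vapply(test_mols, `[[`, numeric(1), "pIC50")
  ok <- !is.na(pred_test)
  if (sum(ok) < 3) stop("fewer than 3 test compounds could be predicted")
  stats_test <- regression_validation_stats(pred_test[ok], obs_test[ok],
                                            legacy_k = legacy_k)
  q2 <- external_q2(pred_test[ok], obs_test[ok])
  r2_train <- stats::cor(model$fitted, model$y_train)^2
  fp <- f_statistic(r2_train, model$n_factors, length(model$y_train))
  stability <- if (!is.null(X_train)) {
    loo_stability(X_train, model$y_train, model$n_factors, model$t_cutoff)
  } else NA_real_
  rep <- c(stats_test, list(
    q2 = q2, r2_train = r2_train, f_value = fp$F, p_value = fp$p,
    stability = stability, m = model$n_factors,
    n_train = length(model$y_train), n_test = sum(ok),
    sd_train = stats::sd(model$y_train - model$fitted),
    rmse_test = stats_test$rmse))
  rep <- accept_model(rep)
  class(rep) <- "qp_validation_report"
  rep
}

#' Apply the model-acceptance rule set
#'
#' The six criteria are evaluated as a conjunction; every violated
#' inequality is reported verbatim in `failed_criteria`.
#'
#' @param report list carrying q2, r2, r0_2, r0p_2, k, rm_2 (a partial
#'   report from [regression_validation_stats()] plus q2 works).
#' @return the report with `accepted` and `failed_criteria` added.
#' @export
accept_model <- function(report) {
  need <- c("q2", "r2", "r0_2", "r0p_2", "k", "rm_2")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0) stop("report lacks fields: ",
                             paste(miss, collapse = ", "))
  failed <- character(0)
  if (!(report$q2 > 0.5)) failed <- c(failed, "q2 > 0.5")
  if (!(report$r2 > 0.6)) failed <- c(failed, "r2 > 0.6")
  if (!((report$r2 - report$r0_2) / report$r2 < 0.1)) {
    failed <- c(failed, "(r2 - r0_2)/r2 < 0.1")
  }
  if (!((report$r2 - report$r0p_2) / report$r2 < 0.1)) {
    failed <- c(failed, "(r2 - r0p_2)/r2 < 0.1")
  }
  if (!(report$k >= 0.85 && report$k <= 1.15)) {
    failed <- c(failed, "0.85 <= k <= 1.15")
  }
  if (!(report$rm_2 > 0.5)) failed <- c(failed, "rm_2 > 0.5")
  report$failed_criteria <- failed
  report$accepted <- length(failed) == 0
  report
}

#' Render validation reports as a statistics table
#'
#' Column order mirrors the conventional model-summary table: ID, SD, R2,
#' F, P, Stability, RMSE, Q2, Pearson, plus the acceptance columns.
#'
#' @param reports named list of `qp_validation_report` objects.
#' @param csv_path optional output CSV.
#' @return data.frame (invisibly when writing).
#' @export
validation_table <- function(reports, csv_path = NULL) {
  rows <- lapply(names(reports), function(id) {
    r <- reports[[id]]
    data.frame(ID = id, SD = r$sd_train, R2 = r$r2_train, F = r$f_value,
               P = r$p_value, Stability = r$stability, RMSE = r$rmse_test,
               Q2 = r$q2, Pearson = r$pearson_r, accepted = r$accepted,
               failed = paste(r$failed_criteria, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
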