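#' Residuals and RMSE between predicted and experimental log K
#'
#' The residual of a solute is predicted minus experimental
#' (`RES_i = log K_lip^pred_i - log K_lip^exp_i`), so systematic
#' underprediction shows up as negative residuals.  The RMSE is the root
#' of the mean squared residual.
#'
#' @param pred,exp paired numeric vectors of base-10 log partition
#'   coefficients (same length, same solute order).
#' @return `prediction_residuals`: numeric vector of residuals;
#'   `prediction_rmse`: scalar RMSE.
#' @export
prediction_residuals <- function(pred, exp) {
  if (length(pred) != length(exp)) {
    .stopf("length mismatch: %d predicted vs %d experimental values",
           length(pred), length(exp))
  }
  if (!length(pred)) .stopf("empty input")
  pred - exp
}

#' @rdname prediction_residuals
#' @export
prediction_rmse <- function(pred, exp) {
  res <- prediction_residuals(pred, exp)
  sqrt(mean(res^2))
}

.require_finite_kow <- function(records) {
  if (!"log_kow" %in% names(records)) .stopf("records lack a log_kow column")
  bad <- records$name[!is.finite(records$log_kow)]
  if (length(bad)) {
    .stopf("missing/non-finite log_kow for: %s", paste(bad, collapse = ", "))
  }
  invisible(records)
}

#' Dataset filters on experimental log K_ow
#'
#' `exclude_extreme_lipophilic()` removes solutes with `log_kow`
#' strictly greater than 5.0: for such extremely lipophilic solutes the
#' measured lipid/water coefficient depends on the lipid content of the
#' sample, so they are dropped before any benchmarking.
#' `reduced_dataset()` removes solutes with `log_kow` strictly below 1,
#' leaving the reduced set (`log_kow >= 1`) used to quantify the
#' systematic underprediction of hydrophilic solutes.  Both filters are
#' idempotent and commute; both require a finite `log_kow` on every record
#' and abort naming the offending solutes otherwise.
#'
#' @param records an `sc_solutes` data.frame (or any data.frame with
#'   `name` and `log_kow` columns).
#' @param threshold filter threshold on `log_kow` (defaults 5.0 / 1.0).
#' @return filtered records; the removed names are attached as the
#'   `removed` attribute.
#' @export
exclude_extreme_lipophilic <- function(records, threshold = 5.0) {
  if (!nrow(records)) {
    attr(records, "removed") <- character(0)
    return(records)
  }
  .require_finite_kow(records)
  drop <- records$log_kow > threshold  # strict: 5.0 itself is retained
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- records$name[drop]
  out
}

#' @rdname exclude_extreme_lipophilic
#' @export
reduced_dataset <- function(records, threshold = 1.0) {
  if (!nrow(records)) {
    attr(records, "removed") <- character(0)
    return(records)
  }
  .require_finite_kow(records)
  drop <- records$log_kow < threshold  # retained set has log_kow >= 1
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- records$name[drop]
  if (!nrow(out)) warning("reduced dataset is empty", call. = FALSE)
  out
}

#' Through-origin QSPR fit of log K_lip against log K_ow
#'
#' Least squares of `y = log_klip` on `x = log_kow` with no intercept:
#' `beta = sum(x*y) / sum(x^2)`; `rmse_fit = sqrt(mean((y - beta*x)^2))`.
#' The Pearson correlation is computed on (x, y) directly and is therefore
#' independent of the fit.
#'
#' @param log_klip base-10 log lipid/water coefficients (response).
#' @param log_kow base-10 log octanol/water coefficients (regressor).
#' @return object of class `sc_qspr`: `beta`, `rmse_fit`, `pearson_R`,
#'   `n_points`, and `beta_se` (the usual through-origin slope standard
#'   error, for recovery checks).
#' @export
qspr_fit <- function(log_klip, log_kow) {
  x <- log_kow
  y <- log_klip
  if (length(x) != length(y)) .stopf("length mismatch in QSPR fit")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) .stopf("QSPR fit needs at least 2 finite pairs")
  sxx <- sum(x^2)
  if (sxx == 0) .stopf("degenerate fit: all log_kow values are zero")
  beta <- sum(x * y) / sxx
  res <- y - beta * x
  rmse_fit <- sqrt(mean(res^2))
  sigma2 <- sum(res^2) / max(1L, n - 1L)
  structure(list(beta = beta, rmse_fit = rmse_fit,
                 pearson_R = stats::cor(x, y), n_points = n,
                 beta_se = sqrt(sigma2 / sxx)),
            class = "sc_qspr")
}

#' @export
print.sc_qspr <- function(x, ...) {
  cat(sprintf("<sc_qspr> beta = %.4f (SE %.4f), RMSE = %.4f, R = %.4f, n = %d\n",
              x$beta, x$beta_se, x$rmse_fit, x$pearson_R, x$n_points))
  invisible(x)
}

#' Quadrant analysis of paired residuals
#'
#' Classifies paired residuals (x = log K_ow residual, y = log K_lip
#' residual) by quadrant: Q1 = (+,+), Q2 = (-,+), Q3 = (-,-), Q4 = (+,-).
#' Pairs with either residual exactly zero sit on an axis and are counted
#' separately, in no quadrant.  The sign-agreement fraction
#' `(Q1 + Q3) / (Q1 + Q2 + Q3 + Q4)` summarizes whether over(under)
#' prediction of log K_ow accompanies over(under)prediction of log K_lip.
#'
#' @param res_klip log K_lip residuals.
#' @param res_kow paired log K_ow residuals.
#' @return list: `Q1`..`Q4` counts, `on_axis`, `agreement`.
#' @export
quadrant_analysis <- function(res_klip, res_kow) {
  if (length(res_klip) != length(res_kow)) .stopf("length mismatch")
  on_axis <- res_klip == 0 | res_kow == 0
  x <- res_kow[!on_axis]
  y <- res_klip[!on_axis]
  q1 <- sum(x > 0 & y > 0)
  q2 <- sum(x < 0 & y > 0)
  q3 <- sum(x < 0 & y < 0)
  q4 <- sum(x > 0 & y < 0)
  tot <- q1 + q2 + q3 + q4
  list(Q1 = q1, Q2 = q2, Q3 = q3, Q4 = q4, on_axis = sum(on_axis),
       agreement = if (tot > 0) (q1 + q3) / tot else NA_real_)
}

#' Per-system benchmark report
#'
#' Mirrors the benchmarking workflow: extreme lipophilics
#' (`log_kow > 5`) are removed once, then for every system with a
#' `log_klip_pred_<system>` column the RMSE against experiment is computed
#' on the full (post-exclusion) and reduced (`log_kow >= 1`) sets,
#' together with through-origin QSPR fits of the predicted log K_lip
#' against experimental `log_kow` and (when present) predicted
#' `log_kow_pred`.  The experimental QSPR fit (log_klip_exp vs log_kow)
#' is reported once alongside.
#'
#' @param records an `sc_solutes` data.frame.
#' @param systems system names; default: every `log_klip_pred_*` column.
#' @return object of class `sc_benchmark`: `table` (one row per system),
#'   `fit_exp` (experimental QSPR fit), `excluded`, `reduced_removed`,
#'   `n_all`, `n_reduced`.
#' @export
benchmark_report <- function(records, systems = NULL) {
  pred_cols <- grep("^log_klip_pred_", names(records), value = TRUE)
  found <- sub("^log_klip_pred_", "", pred_cols)
  if (is.null(systems)) systems <- found
  if (!length(systems)) .stopf("no systems with predictions")
  gaps <- setdiff(systems, found)
  if (length(gaps)) {
    .stopf("missing prediction column(s) for system(s): %s",
           paste(gaps, collapse = ", "))
  }
  kept <- exclude_extreme_lipophilic(records)
  excluded <- attr(kept, "removed")
  red <- reduced_dataset(kept)
  reduced_removed <- attr(red, "removed")

  ## fits need >= 2 points; a one-record system still gets its RMSE
  safe_fit <- function(y, x) {
    if (sum(is.finite(x) & is.finite(y)) < 2L) NULL else qspr_fit(y, x)
  }
  one_system <- function(sys) {
    col <- paste0("log_klip_pred_", sys)
    na_pred <- kept$name[!is.finite(kept[[col]])]
    if (length(na_pred)) {
      .stopf("system %s: missing predictions for %s", sys,
             paste(na_pred, collapse = ", "))
    }
    fit_vs_exp <- safe_fit(kept[[col]], kept$log_kow)
    has_pred_kow <- "log_kow_pred" %in% names(kept) &&
      all(is.finite(kept$log_kow_pred))
    fit_vs_pred <- if (has_pred_kow) safe_fit(kept[[col]], kept$log_kow_pred) else NULL
    data.frame(
      system = sys,
      rmse_all = prediction_rmse(kept[[col]], kept$log_klip_exp),
      rmse_reduced = prediction_rmse(red[[col]], red$log_klip_exp),
      beta_vs_exp_kow = if (is.null(fit_vs_exp)) NA_real_ else fit_vs_exp$beta,
      rmse_fit_vs_exp_kow = if (is.null(fit_vs_exp)) NA_real_ else fit_vs_exp$rmse_fit,
      R_vs_exp_kow = if (is.null(fit_vs_exp)) NA_real_ else fit_vs_exp$pearson_R,
      beta_vs_pred_kow = if (is.null(fit_vs_pred)) NA_real_ else fit_vs_pred$beta,
      rmse_fit_vs_pred_kow = if (is.null(fit_vs_pred)) NA_real_ else fit_vs_pred$rmse_fit,
      R_vs_pred_kow = if (is.null(fit_vs_pred)) NA_real_ else fit_vs_pred$pearson_R,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, lapply(systems, one_system))
  rownames(tab) <- NULL
  structure(list(table = tab,
                 fit_exp = safe_fit(kept$log_klip_exp, kept$log_kow),
                 excluded = excluded, reduced_removed = reduced_removed,
                 n_all = nrow(kept), n_reduced = nrow(red)),
            class = "sc_benchmark")
}

#' @export
print.sc_benchmark <- function(x, ...) {
  cat(sprintf("<sc_benchmark> %d solutes (%d excluded as log_kow > 5), reduced set %d (%d removed as log_kow < 1)\n",
              x$n_all, length(x$excluded), x$n_reduced,
              length(x$reduced_removed)))
  if (!is.null(x$fit_exp)) {
    cat(sprintf("  experimental QSPR: beta = %.3f, RMSE = %.3f, R = %.3f\n",
                x$fit_exp$beta, x$fit_exp$rmse_fit, x$fit_exp$pearson_R))
  }
  print(format(x$table, digits = 3))
  invisible(x)
}
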