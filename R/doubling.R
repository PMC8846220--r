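#' Length of the principal circle in the scaled score plane
#'
#' Quantifies the contraction of a cell cycle trajectory: each of the two
#' phase scores is divided by its maximum, a closed principal curve is
#' fitted to the resulting 2D cloud, and the total polyline length `LP` is
#' returned. Faster-dividing populations have no time to fully degrade
#' mitotic transcripts during G1, which contracts the loop, so `LP`
#' correlates with the population doubling time.
#'
#' @param S_scores,M_scores Per-cell S-phase and G2/M scores (same
#'   length, at least 50 cells).
#' @param q Number of nodes for the principal circle (default 30).
#' @param ... Passed to [fit_principal_curve()].
#' @return Scalar `LP` with attribute `curve` (the fitted circle).
#' @export
principal_circle_length <- function(S_scores, M_scores, q = 30L, ...) {
  stopifnot(length(S_scores) == length(M_scores))
  if (length(S_scores) < 50L) stop("need at least 50 cells")
  if (stats::sd(S_scores) == 0 || stats::sd(M_scores) == 0)
    stop("constant scores")
  pts <- cbind(S = S_scores / max(S_scores), M = M_scores / max(M_scores))
  cv <- fit_principal_curve(pts, q = q, closed = TRUE, ...)
  structure(curve_length(cv), curve = cv)
}

#' Regress doubling time on principal-circle length
#'
#' Ordinary least squares of doubling time (`DT`, hours) on the
#' principal-circle length (`LP`), with an explicit outlier exclusion list
#' (cell lines whose culture-condition-dependent doubling times deviate
#' grossly are excluded by inspection, but still receive predictions).
#' An optional automatic flag marks records whose externally studentized
#' residual exceeds 3.
#'
#' @param records Data frame with columns `dataset_id`, `LP` and `DT`
#'   (`DT` may be `NA` for prediction-only records).
#' @param outlier_ids Character vector of `dataset_id`s excluded from the
#'   fit.
#' @param flag_studentized Also flag `|studentized residual| > 3` records
#'   in the output?
#' @return List with `slope`, `intercept`, `pearson_r`, `p_value`, `n_fit`
#'   and `predictions` (the input records plus `DT_pred`, `excluded`,
#'   and optionally `flagged`).
#' @export
regress_doubling_time <- function(records, outlier_ids = character(0L),
                                  flag_studentized = FALSE) {
  stopifnot(all(c("dataset_id", "LP", "DT") %in% names(records)))
  use <- !records$dataset_id %in% outlier_ids & !is.na(records$DT)
  if (sum(use) < 3L) stop("need at least 3 usable records")
  fit <- stats::lm(DT ~ LP, data = records[use, ])
  ct <- stats::cor.test(records$LP[use], records$DT[use],
                        method = "pearson")
  pred <- records
  pred$DT_pred <- as.numeric(stats::predict(fit, newdata = records))
  pred$excluded <- records$dataset_id %in% outlier_ids
  if (flag_studentized) {
    rs <- rep(NA_real_, nrow(records))
    rs[use] <- stats::rstudent(fit)
    pred$flagged <- !is.na(rs) & abs(rs) > 3
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_fit = sum(use), predictions = pred)
}
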