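#' Activity transform: elongation to pE
#'
#' `pE = log10(100 * E / Emax)`, so the most active compound of a dataset
#' (E = Emax) has pE = 2 exactly. pE differences between compounds do not
#' depend on the choice of Emax.
#'
#' @param E elongation(s), mm; must be > 0.
#' @param Emax reference maximum elongation, mm; defaults to `max(E)`.
#' @return pE value(s), base-10 log units.
#' @export
compute_pE <- function(E, Emax = max(E)) {
  if (any(!is.finite(E)) || any(E <= 0)) stop("E must be positive")
  if (!is.finite(Emax) || Emax <= 0) stop("Emax must be positive")
  log10(100 * E / Emax)
}

#' Build an activity table from elongations
#'
#' @param ids compound labels.
#' @param E elongations, mm.
#' @param Emax reference maximum (dataset maximum by default).
#' @param test_ids compound ids held out as the external test set.
#' @return data frame with `id`, `E_mm`, `pE`, `role` (`"train"`/`"test"`).
#' @export
activity_table <- function(ids, E, Emax = max(E), test_ids = character()) {
  stopifnot(length(ids) == length(E))
  data.frame(id = as.character(ids), E_mm = E, pE = compute_pE(E, Emax),
             role = ifelse(ids %in% test_ids, "test", "train"))
}

#' Predictive r-squared of an external test set
#'
#' `r2_pred = (SD - PRESS) / SD`, with `SD` the sum of squared deviations of
#' the test-set activities from the *training-set* mean activity, and
#' `PRESS` the sum of squared prediction errors on the test set. Can also be
#' evaluated directly from precomputed (SD, PRESS).
#'
#' @param actual observed test-set activities (pE).
#' @param predicted model predictions for the same compounds.
#' @param train_mean mean activity of the training set.
#' @param SD,PRESS optionally supply the two sums directly (then the vector
#'   arguments are ignored).
#' @return list with `SD`, `PRESS`, `r2_pred`.
#' @export
predictive_r2 <- function(actual = NULL, predicted = NULL, train_mean = NULL,
                          SD = NULL, PRESS = NULL) {
  if (is.null(SD) || is.null(PRESS)) {
    stopifnot(length(actual) == length(predicted), length(actual) >= 2L,
              is.numeric(train_mean))
    SD <- sum((actual - train_mean)^2)
    PRESS <- sum((actual - predicted)^2)
  }
  if (SD == 0) stop("SD is zero: predictive r2 undefined")
  list(SD = SD, PRESS = PRESS, r2_pred = (SD - PRESS) / SD)
}

#' Golbraikh-Tropsha external-validation battery
#'
#' Computes, for observed (`y`) and predicted (`yhat`) test-set activities:
#' the squared Pearson correlation `r2`; through-origin slopes in both
#' orientations (`k` for predicted-on-observed, `k_primed` for
#' observed-on-predicted); the corresponding through-origin determination
#' coefficients `r0_sq` and `r0_sq_primed`; and `rm2 = r2 * (1 - sqrt(r2 -
#' r0_sq_primed))`. The primed (observed-regressed-on-predicted)
#' orientation is the one conventionally tabulated, and is the one used for
#' rm2; the other orientation is always reported alongside. Criteria flags:
#' `r2 > 0.6`; `(r2 - r0_sq)/r2 < 0.1` in at least one orientation; `0.85 <=
#' k <= 1.15` in at least one orientation; `rm2 > 0.5`; and `q2 > 0.5` when
#' an internal q2 is supplied.
#'
#' @param actual observed activities (length >= 3).
#' @param predicted predicted activities.
#' @param q2 optional internal LOO q2 of the underlying model.
#' @return a `qsar_tropsha` list of metrics and logical criteria flags.
#' @export
tropsha_battery <- function(actual, predicted, q2 = NA_real_) {
  y <- as.numeric(actual); yh <- as.numeric(predicted)
  stopifnot(length(y) == length(yh))
  if (length(y) < 3L) stop("need at least 3 test compounds")
  if (sd(y) == 0 || sd(yh) == 0) stop("zero-variance vector")
  r2 <- cor(y, yh)^2
  k <- sum(y * yh) / sum(y^2)          # predicted ~ k * observed
  k_primed <- sum(y * yh) / sum(yh^2)  # observed ~ k' * predicted
  r0_sq <- 1 - sum((yh - k * y)^2) / sum((yh - mean(yh))^2)
  r0_sq_primed <- 1 - sum((y - k_primed * yh)^2) / sum((y - mean(y))^2)
  rm2 <- r2 * (1 - sqrt(max(r2 - r0_sq_primed, 0)))
  rm2_unprimed <- r2 * (1 - sqrt(max(r2 - r0_sq, 0)))
  gap <- (r2 - r0_sq) / r2
  gap_primed <- (r2 - r0_sq_primed) / r2
  crit <- list(q2_gt_0.5 = if (is.na(q2)) NA else q2 > 0.5,
               r2_gt_0.6 = r2 > 0.6,
               r0_gap_lt_0.1 = (gap < 0.1) || (gap_primed < 0.1),
               k_in_range = (k >= 0.85 && k <= 1.15) ||
                 (k_primed >= 0.85 && k_primed <= 1.15),
               rm2_gt_0.5 = rm2 > 0.5)
  structure(list(n = length(y), q2 = q2, r2 = r2, k = k, k_primed = k_primed,
                 r0_sq = r0_sq, r0_sq_primed = r0_sq_primed,
                 r2_gap = gap, r2_gap_primed = gap_primed,
                 rm2 = rm2, rm2_unprimed = rm2_unprimed,
                 criteria = crit,
                 pass = all(unlist(crit), na.rm = TRUE)),
            class = "qsar_tropsha")
}

#' @export
print.qsar_tropsha <- function(x, ...) {
  cat("<qsar_tropsha> external validation, n =", x$n, "\n")
  cat(sprintf("  r2 = %.3f | k = %.3f, k' = %.3f | r0^2 = %.3f, r0'^2 = %.3f\n",
              x$r2, x$k, x$k_primed, x$r0_sq, x$r0_sq_primed))
  cat(sprintf("  rm2 = %.3f (unprimed %.3f) | criteria %s\n", x$rm2,
              x$rm2_unprimed, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Full external-validation report
#'
#' Combines [predictive_r2()] and [tropsha_battery()] for one model.
#'
#' @param actual,predicted test-set activities.
#' @param train_mean training-set mean activity.
#' @param q2 internal LOO q2 (optional).
#' @return list with `SD`, `PRESS`, `r2_pred` and the `tropsha` battery.
#' @export
validation_report <- function(actual, predicted, train_mean,
                              q2 = NA_real_) {
  pr <- predictive_r2(actual, predicted, train_mean)
  c(pr, list(tropsha = tropsha_battery(actual, predicted, q2 = q2)))
}
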