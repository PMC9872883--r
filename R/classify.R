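# Two-group diagnosis: single scalar threshold on one statistical moment,
# chosen to maximize balanced accuracy, with sensitivity/specificity
# reporting and the accuracy grading scale.

# Contingency counts for a threshold rule.  `direction` "ge" calls carcinoma
# when value >= threshold, "le" when value <= threshold; ties (values equal
# to the threshold) therefore always fall on the carcinoma side.
.count_calls <- function(carcinoma, adenoma, threshold, direction) {
  carc_call <- function(v) if (direction == "ge") v >= threshold else v <= threshold
  a <- sum(carc_call(carcinoma))        # correct carcinoma calls
  b <- length(carcinoma) - a            # missed carcinoma
  c_ <- sum(!carc_call(adenoma))        # correct adenoma calls
  d <- length(adenoma) - c_             # missed adenoma
  c(a = a, b = b, c = c_, d = d)
}

.se_sp_ac <- function(cnt) {
  se <- 100 * cnt[["a"]] / (cnt[["a"]] + cnt[["b"]])
  sp <- 100 * cnt[["c"]] / (cnt[["c"]] + cnt[["d"]])
  c(Se = se, Sp = sp, Ac = (se + sp) / 2)
}

# Exhaustive sweep over candidate thresholds (the observed values plus +-Inf,
# which keeps the rule invariant under strictly monotone transforms) and both
# directions.  Deterministic tie-break: higher Ac, then direction "ge", then
# smaller threshold.
.fit_threshold <- function(carcinoma, adenoma) {
  cand <- sort(unique(c(carcinoma, adenoma)))
  cand <- c(-Inf, cand, Inf)
  best <- NULL
  for (direction in c("ge", "le")) {
    for (thr in cand) {
      cnt <- .count_calls(carcinoma, adenoma, thr, direction)
      ac <- .se_sp_ac(cnt)[["Ac"]]
      if (is.null(best) || ac > best$ac + 1e-12) {
        best <- list(threshold = thr, direction = direction, ac = ac)
      }
    }
  }
  best
}

#' Grade a balanced accuracy
#'
#' Accuracy grading scale: below 70% Unsatisfactory, 70-80% Satisfactory,
#' 81-90% Good, 91-100% Excellent.  Accuracies in the open gaps are resolved
#' by rounding to the nearest integer first.
#'
#' @param ac Balanced accuracy in percent, in `[0, 100]`.
#' @return Character grade label.
#' @examples
#' grade_accuracy(86)  # "Good"
#' @export
grade_accuracy <- function(ac) {
  stopifnot(is.numeric(ac), all(ac >= 0 & ac <= 100))
  r <- round(ac)
  ifelse(r < 70, "Unsatisfactory",
         ifelse(r <= 80, "Satisfactory",
                ifelse(r <= 90, "Good", "Excellent")))
}

#' Single-threshold diagnostic classifier
#'
#' Fits the scalar threshold (and direction) on one moment value per sample
#' that maximizes balanced accuracy `Ac = (Se + Sp)/2` between the carcinoma
#' and adenoma groups.  The reported operating characteristics use
#' leave-one-out cross-validation by default: each sample is classified by
#' the threshold fitted on the remaining samples, so the quoted Se/Sp/Ac are
#' out-of-sample.  `scheme = "resubstitution"` reports the training-set
#' characteristics instead.
#'
#' @param carcinoma,adenoma Numeric vectors of the feature (one moment of one
#'   observable) per sample; at least 2 samples per group.
#' @param scheme `"loo"` (default) or `"resubstitution"`.
#' @return Object of class `mm_classifier`: the fitted `threshold`,
#'   `direction`, contingency `counts` (a, b, c, d), `Se`, `Sp`, `Ac`
#'   (percent), `grade`, and `scheme`.
#' @examples
#' fit <- threshold_classifier(carcinoma = c(5, 6, 7, 8), adenoma = c(1, 2, 3, 4))
#' fit$Ac  # 100
#' @export
threshold_classifier <- function(carcinoma, adenoma,
                                 scheme = c("loo", "resubstitution")) {
  scheme <- match.arg(scheme)
  carcinoma <- as.numeric(carcinoma); adenoma <- as.numeric(adenoma)
  stopifnot(length(carcinoma) >= 2L, length(adenoma) >= 2L,
            all(is.finite(carcinoma)), all(is.finite(adenoma)))
  degenerate <- length(unique(c(carcinoma, adenoma))) == 1L
  if (degenerate)
    warning("identical values in both groups: chance-level classifier",
            call. = FALSE)
  fit <- .fit_threshold(carcinoma, adenoma)
  if (scheme == "resubstitution") {
    cnt <- .count_calls(carcinoma, adenoma, fit$threshold, fit$direction)
  } else {
    cnt <- c(a = 0, b = 0, c = 0, d = 0)
    for (i in seq_along(carcinoma)) {
      f <- .fit_threshold(carcinoma[-i], adenoma)
      hit <- .count_calls(carcinoma[i], numeric(0), f$threshold, f$direction)[["a"]]
      cnt["a"] <- cnt[["a"]] + hit
      cnt["b"] <- cnt[["b"]] + (1 - hit)
    }
    for (i in seq_along(adenoma)) {
      f <- .fit_threshold(carcinoma, adenoma[-i])
      ok <- .count_calls(numeric(0), adenoma[i], f$threshold, f$direction)[["c"]]
      cnt["c"] <- cnt[["c"]] + ok
      cnt["d"] <- cnt[["d"]] + (1 - ok)
    }
  }
  perf <- .se_sp_ac(cnt)
  structure(list(threshold = fit$threshold, direction = fit$direction,
                 counts = cnt, Se = perf[["Se"]], Sp = perf[["Sp"]],
                 Ac = perf[["Ac"]], grade = grade_accuracy(perf[["Ac"]]),
                 scheme = scheme,
                 data = list(carcinoma = carcinoma, adenoma = adenoma)),
            class = "mm_classifier")
}

#' Diagnostic performance from contingency counts
#'
#' `Se = a/(a+b) * 100`, `Sp = c/(c+d) * 100`, `Ac = (Se + Sp)/2`, where `a`
#' and `b` count correct and missed carcinoma diagnoses and `c`, `d` the same
#' for adenoma.
#'
#' @param a,b,c,d Non-negative integer counts; `a+b >= 1` and `c+d >= 1`.
#' @return Named vector `c(Se, Sp, Ac)` in percent.
#' @examples
#' diagnostic_performance(24, 2, 22, 4)  # Se 92.3, Sp 84.6, Ac 88.5
#' @export
diagnostic_performance <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b >= 1, c + d >= 1)
  .se_sp_ac(c(a = a, b = b, c = c, d = d))
}

#' @export
print.mm_classifier <- function(x, ...) {
  cat(sprintf("Threshold classifier (%s): carcinoma if value %s %.6g\n",
              x$scheme, if (x$direction == "ge") ">=" else "<=", x$threshold))
  cat(sprintf("  Se = %.1f%%  Sp = %.1f%%  Ac = %.1f%%  [%s]\n",
              x$Se, x$Sp, x$Ac, x$grade))
  cat(sprintf("  counts: a = %d, b = %d, c = %d, d = %d\n",
              x$counts[["a"]], x$counts[["b"]], x$counts[["c"]],
              x$counts[["d"]]))
  invisible(x)
}

#' @export
summary.mm_classifier <- function(object, ...) {
  print(object)
  cat(sprintf("  groups: %d carcinoma, %d adenoma samples\n",
              length(object$data$carcinoma), length(object$data$adenoma)))
  invisible(object)
}

#' Predict group labels with a fitted threshold classifier
#'
#' @param object An `mm_classifier`.
#' @param newdata Numeric vector of feature values.
#' @param ... Unused.
#' @return Character vector `"carcinoma"`/`"adenoma"`.
#' @export
predict.mm_classifier <- function(object, newdata, ...) {
  v <- as.numeric(newdata)
  carc <- if (object$direction == "ge") v >= object$threshold else v <= object$threshold
  ifelse(carc, "carcinoma", "adenoma")
}
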