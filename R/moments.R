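# First- to fourth-order statistical moments of anisotropy maps and cohort
# summaries.  The "literal" moment set is Z1 = mean(OA), Z2 = mean(OA^2),
# Z3 = mean(OA^3)/Z2^3, Z4 = mean(OA^4)/Z2^4, evaluated over valid pixels.

#' Statistical moments Z1..Z4 of a map
#'
#' The default `literal` mode evaluates `Z1 = mean(x)`, `Z2 = mean(x^2)`,
#' `Z3 = mean(x^3) / Z2^3`, `Z4 = mean(x^4) / Z2^4` over the valid pixels.
#' Because the higher orders are normalized by powers of `Z2`, weakly
#' anisotropic maps (values around 1e-3) produce `Z3`/`Z4` that are orders of
#' magnitude more responsive than `Z1`/`Z2`, which is what makes them useful
#' diagnostic markers.
#'
#' The optional `centered` mode gives the classical mean, variance, skewness
#' and excess kurtosis; it is never the default.
#'
#' @param x Numeric matrix (an anisotropy map) or vector.
#' @param mask Optional logical mask of valid pixels (NA/NaN pixels are
#'   always dropped).
#' @param mode `"literal"` (default) or `"centered"`.
#' @param observable,phase_plane Optional metadata labels.
#' @return Named numeric vector `c(Z1, Z2, Z3, Z4)` of class `mm_moments`
#'   with attributes `P` (valid pixel count), `mode`, and `flagged` (TRUE for
#'   an all-zero map, where `Z3 = Z4 = 0` by convention).
#' @examples
#' mm_moments(c(1, 2, 3, 4))  # Z1 = 2.5, Z2 = 7.5
#' @export
mm_moments <- function(x, mask = NULL, mode = c("literal", "centered"),
                       observable = NULL, phase_plane = NULL) {
  mode <- match.arg(mode)
  v <- as.numeric(x)
  keep <- is.finite(v)
  if (!is.null(mask)) keep <- keep & as.logical(mask)
  v <- v[keep]
  if (length(v) < 1L) stop("no valid pixels")
  flagged <- FALSE
  if (mode == "literal") {
    z1 <- mean(v); z2 <- mean(v^2)
    if (z2 == 0) {
      z3 <- z4 <- 0
      flagged <- TRUE
    } else {
      z3 <- mean(v^3) / z2^3
      z4 <- mean(v^4) / z2^4
    }
  } else {
    z1 <- mean(v)
    z2 <- mean((v - z1)^2)
    if (z2 == 0) {
      z3 <- z4 <- 0
      flagged <- TRUE
    } else {
      z3 <- mean((v - z1)^3) / z2^1.5
      z4 <- mean((v - z1)^4) / z2^2 - 3
    }
  }
  structure(c(Z1 = z1, Z2 = z2, Z3 = z3, Z4 = z4),
            class = "mm_moments", P = length(v), mode = mode,
            observable = observable, phase_plane = phase_plane,
            flagged = flagged)
}

#' @export
print.mm_moments <- function(x, digits = 5, ...) {
  lab <- attr(x, "observable")
  pp <- attr(x, "phase_plane")
  cat(sprintf("Moments%s%s (P = %d, %s)%s\n",
              if (!is.null(lab)) paste0(" of ", lab) else "",
              if (!is.null(pp)) sprintf(" at phi = %.3g rad", pp) else "",
              attr(x, "P"), attr(x, "mode"),
              if (isTRUE(attr(x, "flagged"))) " [all-zero map]" else ""))
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(signif(v, digits))
  invisible(x)
}

#' Moments of every observable in an anisotropy map set
#'
#' @param maps An `anisotropy_maps` object (see [layered_anisotropy()]).
#' @param mode Passed to [mm_moments()].
#' @return Named list of `mm_moments`, one per observable.
#' @export
map_set_moments <- function(maps, mode = "literal") {
  stopifnot(inherits(maps, "anisotropy_maps"))
  obs <- c("phi_L", "phi_circ", "delta_L", "delta_circ")
  setNames(lapply(obs, function(o)
    mm_moments(maps[[o]], mask = maps$valid, mode = mode,
               observable = o, phase_plane = maps$phase_plane)), obs)
}

#' Cohort summary of moment vectors
#'
#' Per-moment mean and standard deviation across a cohort of samples.
#'
#' @param Z Numeric matrix (samples x moments), data.frame, or list of
#'   `mm_moments` vectors.
#' @param population Use the population (divide by n) instead of the sample
#'   (divide by n-1) standard deviation.  Default FALSE.
#' @return data.frame with columns `moment`, `mean`, `sd`, `n`.
#' @examples
#' cohort_summary(rbind(c(0.5, 1, 1, 1), c(0.7, 1, 1, 1)))
#' @export
cohort_summary <- function(Z, population = FALSE) {
  Z <- .as_moment_matrix(Z)
  if (nrow(Z) < 2L) stop("cohort_summary needs at least 2 samples")
  n <- nrow(Z)
  mu <- colMeans(Z)
  s <- apply(Z, 2, sd)
  if (population) s <- s * sqrt((n - 1) / n)
  data.frame(moment = colnames(Z), mean = unname(mu), sd = unname(s), n = n,
             row.names = NULL)
}

.as_moment_matrix <- function(Z) {
  if (is.list(Z) && !is.data.frame(Z)) Z <- do.call(rbind, lapply(Z, unclass))
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  Z
}

#' Cross-validation stability of cohort moments
#'
#' Splits the cohort into `k` disjoint folds, computes [cohort_summary()]
#' within each fold, and reports the largest per-moment variance (squared
#' standard deviation) observed in any fold against the stability bound.
#' A cohort is statistically adequate when every moment's variance stays at
#' or below the bound.
#'
#' Because the literal higher-order moments scale as inverse powers of the
#' map level (a weakly anisotropic map has `Z3`/`Z4` orders of magnitude
#' larger than `Z1`), the default compares moments normalized by their
#' cohort mean, so the bound reads "squared coefficient of variation at most
#' 0.025" uniformly across moments and observables.  Set `relative = FALSE`
#' to test raw variances.
#'
#' @param Z Cohort of moment vectors, as in [cohort_summary()].
#' @param k Number of folds (default 6).
#' @param bound Variance bound (default 0.025).
#' @param relative Normalize each moment by its cohort mean first (default
#'   TRUE).
#' @return List of class `mm_stability`: `pass`, `max_variance`,
#'   `per_moment` (max variance across folds for each moment),
#'   `fold_mean_variance` (variance of the fold means), `k`, `bound`.
#' @export
stability_check <- function(Z, k = 6, bound = 0.025, relative = TRUE) {
  Z <- .as_moment_matrix(Z)
  n <- nrow(Z)
  if (n < 2L) stop("stability_check needs at least 2 samples")
  if (relative) {
    mu <- colMeans(Z)
    mu[mu == 0] <- 1
    Z <- sweep(Z, 2, mu, "/")
  }
  k <- max(2L, min(as.integer(k), n %/% 2L))
  fold <- rep(seq_len(k), length.out = n)
  per_fold <- sapply(seq_len(k), function(f)
    apply(Z[fold == f, , drop = FALSE], 2, var))
  per_fold <- matrix(per_fold, ncol = k,
                     dimnames = list(colnames(Z), NULL))
  fold_means <- t(sapply(seq_len(k), function(f)
    colMeans(Z[fold == f, , drop = FALSE])))
  per_moment <- apply(per_fold, 1, max, na.rm = TRUE)
  structure(list(pass = all(per_moment <= bound),
                 max_variance = max(per_moment),
                 per_moment = per_moment,
                 fold_mean_variance = apply(fold_means, 2, var),
                 k = k, bound = bound),
            class = "mm_stability")
}

#' @export
print.mm_stability <- function(x, ...) {
  cat(sprintf("Cross-validation stability (k = %d): %s\n", x$k,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max per-moment variance %.4g (bound %.3g)\n",
              x$max_variance, x$bound))
  invisible(x)
}
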