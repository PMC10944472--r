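# Motif-additive model (MAM): a mechanistic expression model where the
# output is core promoter level x calibrated activator boost x a single
# two-fold attenuation when any repressing motif is present.

#' Fit / construct a motif-additive expression model
#'
#' Predicted expression for a motif cassette is
#' `core_level * calibration(sum of activator boost weights) * attenuation`,
#' where the attenuation factor is applied exactly once if the cassette
#' contains one or more repressing motifs (attenuation was observed to be a
#' constant roughly two-fold scale-down independent of the number of
#' repressors, while boosting is additive). Boost weights are typically the
#' `-log10` exact mHG p-values of the activating motifs, mapped to a fold
#' change through a linear calibration with `calibration(0) = intercept = 1`
#' so a motif-free cassette predicts the bare core level.
#'
#' @param boost_weights Named non-negative numeric vector: activating motif
#'   id -> boost weight.
#' @param repressors Character vector of repressing motif ids.
#' @param attenuation_factor Multiplicative factor applied once when any
#'   repressor is present; default 0.5 (the observed ~x2 down-regulation).
#' @param core_levels Named numeric vector of baseline core-promoter
#'   expression levels.
#' @param calibration Numeric `c(intercept, slope)` mapping the summed boost
#'   weight to a fold change (default `c(1, 0)`: uncalibrated, fold 1).
#' @return Object of class `mam` with `coef()`, `print()` and `predict()`
#'   methods.
#' @export
mam <- function(boost_weights = numeric(0), repressors = character(0),
                attenuation_factor = 0.5,
                core_levels = c(core = 1), calibration = c(intercept = 1, slope = 0)) {
  if (any(boost_weights < 0)) stopf("boost weights must be non-negative")
  if (!(attenuation_factor > 0 && attenuation_factor <= 1))
    stopf("attenuation_factor must lie in (0, 1]")
  if (is.null(names(core_levels))) stopf("core_levels must be named")
  structure(list(boost_weights = boost_weights, repressors = repressors,
                 attenuation_factor = attenuation_factor,
                 core_levels = core_levels,
                 calibration = c(intercept = unname(calibration[1]),
                                 slope = unname(calibration[2]))),
            class = "mam")
}

#' Build a MAM from mHG enrichment results
#'
#' Activating motifs get boost weight `-log10(p_exact)` from their
#' up-direction result; motifs classified repressing form the repressor set.
#'
#' @param classification Result of [classify_motifs()].
#' @param ... Passed to [mam()] (attenuation, core levels, calibration).
#' @return A [mam()] object.
#' @export
mam_from_mhg <- function(classification, ...) {
  act <- classification[classification$class == "activating", ]
  rep_ <- classification$motif_id[classification$class == "repressing"]
  mam(boost_weights = stats::setNames(-log10(act$p_up), act$motif_id),
      repressors = rep_, ...)
}

#' @export
coef.mam <- function(object, ...) object$boost_weights

#' @export
print.mam <- function(x, ...) {
  cat(sprintf(paste0("Motif-additive model: %d activating motif(s), ",
                     "%d repressor(s), attenuation %.2f\n",
                     "fold = %.3g + %.3g * sum(boost); core levels: %s\n"),
              length(x$boost_weights), length(x$repressors),
              x$attenuation_factor, x$calibration["intercept"],
              x$calibration["slope"],
              paste(sprintf("%s=%.3g", names(x$core_levels), x$core_levels),
                    collapse = ", ")))
  invisible(x)
}

#' Predict expression for motif cassettes
#'
#' @param object A [mam()].
#' @param motif_lists List of character vectors (motif ids per cassette); a
#'   single character vector is treated as one cassette. Motifs absent from
#'   both the boost table and the repressor set are neutral.
#' @param core Name of the core promoter (must exist in `core_levels`).
#' @param ... Unused.
#' @return Data.frame with `fold` (regulatory fold vs the bare core) and
#'   `expression` (A.U. on the core's scale).
#' @export
predict.mam <- function(object, motif_lists, core = names(object$core_levels)[1],
                        ...) {
  if (is.character(motif_lists)) motif_lists <- list(motif_lists)
  if (!core %in% names(object$core_levels))
    stopf("unknown core promoter '%s'", core)
  fold <- vapply(motif_lists, function(ms) {
    # repetition counts: each occurrence contributes its boost weight
    wsum <- sum(object$boost_weights[ms[ms %in% names(object$boost_weights)]])
    f <- object$calibration["intercept"] + object$calibration["slope"] * wsum
    if (any(ms %in% object$repressors)) f <- f * object$attenuation_factor
    unname(f)
  }, numeric(1))
  data.frame(fold = fold,
             expression = fold * object$core_levels[[core]])
}

#' Calibrate the boost-to-fold map from measured cassettes
#'
#' Least-squares line of measured fold regulation against the mean
#' `-log10(p)` of the motifs in each cassette; the observed linear dependence
#' of fold boost on the mHG evidence justifies the linear form.
#'
#' @param observed_folds Measured fold changes (>= 3 cassettes).
#' @param mean_log10_pvalues Mean `-log10` mHG p-value per cassette.
#' @return List `intercept`, `slope`, `r` (Pearson), `fit` (the `lm`).
#' @export
fit_mam_calibration <- function(observed_folds, mean_log10_pvalues) {
  stopifnot(length(observed_folds) == length(mean_log10_pvalues))
  if (length(observed_folds) < 3L) stopf("need at least 3 cassettes")
  if (stats::sd(mean_log10_pvalues) == 0)
    stopf("degenerate calibration: all cassettes have equal mHG evidence")
  fit <- stats::lm(observed_folds ~ mean_log10_pvalues)
  r <- if (stats::sd(observed_folds) == 0) NA_real_
       else stats::cor(observed_folds, mean_log10_pvalues)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]), r = r, fit = fit)
}
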