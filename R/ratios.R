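#' Interhomolog/intersister bias summary
#'
#' Ratio arithmetic on quantified double-Holliday-junction signals. The
#' IH/IS ratio measures homolog template bias: the signal from dHJs joining
#' homologous chromatids divided by the signal from dHJs joining sister
#' chromatids. The interhomolog fraction is `r / (1 + r)`.
#'
#' Censored measurements propagate as bounds: when the IH signal is a
#' detection limit the ratio is an upper bound (`bound = "upper"`); a zero
#' IS signal yields a lower bound on the ratio.
#'
#' @param ih_signal,is_signal non-negative signals (same units, e.g. percent
#'   of total lane signal).
#' @param bound `"exact"` (default), `"upper"` or `"lower"` — the censoring
#'   status of the inputs.
#' @return object of class `bias_summary`: list with `ih_is_ratio`,
#'   `ih_fraction`, `bound`.
#' @examples
#' ih_is_ratio(5.7, 1)    # wild-type-like homolog bias
#' ih_is_ratio(0.22, 1)   # inverted, sister-biased
#' @export
ih_is_ratio <- function(ih_signal, is_signal, bound = c("exact", "upper",
                                                        "lower")) {
  bound <- match.arg(bound)
  if (ih_signal < 0 || is_signal < 0)
    stop("signals must be non-negative", call. = FALSE)
  if (is_signal == 0) {
    if (ih_signal == 0) stop("both signals are zero", call. = FALSE)
    r <- Inf
    bound <- "lower"
  } else {
    r <- ih_signal / is_signal
  }
  structure(
    list(ih_is_ratio = r, ih_fraction = r / (1 + r), bound = bound),
    class = "bias_summary"
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  pre <- switch(x$bound, exact = "", upper = "<= ", lower = ">= ")
  cat(sprintf("IH/IS ratio: %s%.3g (IH fraction %s%.3f)\n",
              pre, x$ih_is_ratio, pre, x$ih_fraction))
  invisible(x)
}

#' Crossover fraction/ratio conversions
#'
#' `co_fraction_to_ratio()` converts the fraction `p` of recombination
#' events resolved as crossovers into the crossover/non-crossover ratio
#' `p / (1 - p)`; `co_ratio_to_fraction()` is its inverse, `r / (1 + r)`.
#'
#' @param p crossover fraction in `[0, 1)`.
#' @param r crossover/non-crossover ratio, non-negative.
#' @return the converted value (vectorised).
#' @examples
#' co_fraction_to_ratio(0.70)   # 2.33
#' co_ratio_to_fraction(1.6)    # 0.615
#' @export
co_fraction_to_ratio <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    stop("`p` must lie in [0, 1)", call. = FALSE)
  p / (1 - p)
}

#' @rdname co_fraction_to_ratio
#' @export
co_ratio_to_fraction <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("`r` must be a non-negative finite number", call. = FALSE)
  r / (1 + r)
}

#' Fold change
#'
#' Simple ratio of two positive quantities, reported as the larger over the
#' smaller unless `direction = "raw"`.
#'
#' @param from,to positive values.
#' @param direction `"auto"` (larger/smaller) or `"raw"` (`to/from`).
#' @return the fold change.
#' @examples
#' fold_change(41, 9.5)      # 4.3-fold decrease
#' fold_change(0.47, 1.51)   # 3.2-fold increase
#' @export
fold_change <- function(from, to, direction = c("auto", "raw")) {
  direction <- match.arg(direction)
  if (any(c(from, to) <= 0)) stop("values must be positive", call. = FALSE)
  if (direction == "raw") return(to / from)
  pmax(from, to) / pmin(from, to)
}

#' Crossover-bias compensation model
#'
#' Quantifies how far an increase in the crossover/non-crossover outcome
#' bias can compensate for a loss of interhomolog template bias, holding the
#' number of recombination events fixed. With `ihf` the interhomolog dHJ
#' fraction and `cof` the crossover fraction among interhomolog events, the
#' expected crossover level is proportional to `ihf * cof`, so the predicted
#' mutant/wild-type relative crossover level is
#' \deqn{\frac{ihf_{mut} \cdot cof_{mut}}{ihf_{wt} \cdot cof_{wt}}}
#'
#' When the observed fold reduction in crossovers is supplied, the model
#' also reports the fraction of the *apparent compensation* attributable to
#' crossover bias on the log scale: the template-bias defect alone predicts
#' a fold reduction `ihf_wt / ihf_mut`; the gap between that prediction and
#' the observed reduction is the apparent compensation, and the share closed
#' by the crossover-bias term is
#' `log(bias_only / predicted) / log(bias_only / observed)`. Any remainder
#' is unexplained compensation, operationally attributed to changes in event
#' number (e.g. additional DSB formation), which this model deliberately
#' excludes.
#'
#' @param wt,mut `bias_summary` objects (from [ih_is_ratio()]) for the
#'   reference and test strains.
#' @param wt_co_fraction,mut_co_fraction crossover fractions among
#'   interhomolog events, in (0, 1).
#' @param observed_fold_reduction optional observed fold reduction in
#'   crossover level (wild type / mutant, > 0).
#' @return object of class `compensation_model`: list with
#'   `predicted_relative_co`, `predicted_fold_reduction`,
#'   `bias_only_fold_reduction`, `observed_fold_reduction`,
#'   `attributable_fraction` (NA without an observed value),
#'   `unexplained_fold` (observed vs predicted remainder, NA likewise).
#' @examples
#' wt <- ih_is_ratio(4.5, 1)
#' mut <- ih_is_ratio(0.15, 1)
#' compensation_model(wt, mut, wt_co_fraction = 0.5,
#'                    mut_co_fraction = 4.9 / 5.9,
#'                    observed_fold_reduction = 2.1)
#' @export
compensation_model <- function(wt, mut, wt_co_fraction, mut_co_fraction,
                               observed_fold_reduction = NULL) {
  stopifnot(inherits(wt, "bias_summary"), inherits(mut, "bias_summary"))
  fr <- c(wt$ih_fraction, mut$ih_fraction, wt_co_fraction, mut_co_fraction)
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr >= 1))
    stop("all fractions must lie strictly in (0, 1)", call. = FALSE)
  predicted <- (mut$ih_fraction * mut_co_fraction) /
    (wt$ih_fraction * wt_co_fraction)
  bias_only <- wt$ih_fraction / mut$ih_fraction
  pred_fold <- 1 / predicted
  attributable <- NA_real_
  unexplained <- NA_real_
  if (!is.null(observed_fold_reduction)) {
    if (observed_fold_reduction <= 0)
      stop("`observed_fold_reduction` must be positive", call. = FALSE)
    attributable <- log(bias_only / pred_fold) /
      log(bias_only / observed_fold_reduction)
    unexplained <- pred_fold / observed_fold_reduction
  }
  structure(
    list(predicted_relative_co = predicted,
         predicted_fold_reduction = pred_fold,
         bias_only_fold_reduction = bias_only,
         observed_fold_reduction = observed_fold_reduction,
         attributable_fraction = attributable,
         unexplained_fold = unexplained),
    class = "compensation_model"
  )
}

#' @export
print.compensation_model <- function(x, ...) {
  cat(sprintf(
    "predicted relative crossover level: %.3f (%.1f-fold reduction)\n",
    x$predicted_relative_co, x$predicted_fold_reduction))
  cat(sprintf("  template-bias defect alone predicts %.1f-fold\n",
              x$bias_only_fold_reduction))
  if (!is.null(x$observed_fold_reduction) &&
      !is.na(x$attributable_fraction)) {
    cat(sprintf(
      "  observed %.1f-fold; crossover bias accounts for %.0f%% of apparent compensation\n",
      x$observed_fold_reduction, 100 * x$attributable_fraction))
    cat(sprintf("  unexplained compensation: %.1f-fold\n", x$unexplained_fold))
  }
  invisible(x)
}
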