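#' Air-quality model evaluation statistics
#'
#' Computes the standard suite of model-performance measures for a paired
#' series of observed (`O`) and predicted (`P`) concentrations:
#' \itemize{
#'   \item `r` — Pearson correlation coefficient;
#'   \item `FAC2` — fraction of pairs with `0.5 <= P/O <= 2` (endpoints
#'     inclusive);
#'   \item `FB` — fractional bias `(mean(O) - mean(P)) / (0.5 (mean(O) +
#'     mean(P)))`, signed so that positive FB means underprediction;
#'   \item `MG` — geometric mean bias `exp(mean(ln O) - mean(ln P))`;
#'   \item `NMSE` — normalized mean square error
#'     `mean((O - P)^2) / (mean(O) mean(P))`;
#'   \item `VG` — geometric variance `exp(mean((ln O - ln P)^2))`.
#' }
#' The logarithmic measures (MG, VG) require positive values; pairs with
#' `O = 0` or `P = 0` are excluded from them with a message, and the whole
#' computation errors if more than 10% of pairs would be dropped. Negative
#' values are rejected. With zero variance in either series `r` is
#' undefined and reported as `NA`.
#'
#' @param O observed values (length >= 2).
#' @param P predicted values, same length.
#' @return an object of class `cabin_eval_report`: a list with the six
#'   statistics, the sample size `n`, the number of pairs excluded from the
#'   log measures, and `criteria` (see [criteria_check()]).
#' @export
#' @examples
#' r <- compute_metrics(O = c(10, 20, 30), P = c(11, 18, 33))
#' r$FB; r$criteria$all_pass
compute_metrics <- function(O, P) {
  O <- as.numeric(O); P <- as.numeric(P)
  if (length(O) != length(P)) stop("O and P must have equal length")
  if (length(O) < 2) stop("need at least two paired values")
  if (anyNA(O) || anyNA(P)) stop("missing values are not allowed")
  if (any(O < 0) || any(P < 0)) stop("concentrations must be non-negative")

  r <- if (stats::sd(O) == 0 || stats::sd(P) == 0) {
    message("zero variance in a series: Pearson r undefined, reported as NA")
    NA_real_
  } else stats::cor(O, P)

  # FAC2: an exact-zero pair (O = P = 0) counts as within a factor of two
  within2 <- ifelse(O == 0, P == 0, P / O >= 0.5 & P / O <= 2)
  FAC2 <- mean(within2)

  FB <- (mean(O) - mean(P)) / (0.5 * (mean(O) + mean(P)))
  NMSE <- mean((O - P)^2) / (mean(O) * mean(P))

  pos <- O > 0 & P > 0
  n_excl <- sum(!pos)
  if (n_excl > 0) {
    if (n_excl > 0.1 * length(O))
      stop("more than 10% of pairs have zero values: ",
           "log-based measures (MG, VG) are not meaningful")
    message(n_excl, " pair(s) with zero values excluded from MG/VG")
  }
  lr <- log(O[pos]) - log(P[pos])
  MG <- exp(mean(lr))
  VG <- exp(mean(lr^2))

  rep <- structure(list(r = r, FAC2 = FAC2, FB = FB, MG = MG, NMSE = NMSE,
                        VG = VG, n = length(O), n_excluded_log = n_excl),
                   class = "cabin_eval_report")
  rep$criteria <- criteria_check(rep)
  rep
}

#' Build an evaluation report from already-computed statistics
#'
#' Useful for checking published statistics against the acceptance
#' criteria without the underlying series.
#'
#' @param r,FAC2,FB,MG,NMSE,VG the six statistics.
#' @param n optional sample size.
#' @return a `cabin_eval_report`.
#' @export
eval_report <- function(r, FAC2, FB, MG, NMSE, VG, n = NA_integer_) {
  if (!is.na(FAC2) && (FAC2 < 0 || FAC2 > 1)) stop("FAC2 must lie in [0, 1]")
  if (!is.na(VG) && VG < 1) stop("VG must be >= 1")
  if (!is.na(NMSE) && NMSE < 0) stop("NMSE must be >= 0")
  if (!is.na(MG) && MG <= 0) stop("MG must be positive")
  rep <- structure(list(r = r, FAC2 = FAC2, FB = FB, MG = MG, NMSE = NMSE,
                        VG = VG, n = n, n_excluded_log = 0L),
                   class = "cabin_eval_report")
  rep$criteria <- criteria_check(rep)
  rep
}

#' @export
print.cabin_eval_report <- function(x, ...) {
  cat("<model evaluation report>\n")
  cat(sprintf("  r = %.3f  FAC2 = %.3f  FB = %+.3f  MG = %.3f  NMSE = %.3f  VG = %.3f\n",
              x$r, x$FAC2, x$FB, x$MG, x$NMSE, x$VG))
  ok <- x$criteria
  cat("  criteria:",
      paste(sprintf("%s[%s]", names(ok)[names(ok) != "all_pass"],
                    ifelse(unlist(ok[names(ok) != "all_pass"]), "pass", "FAIL")),
            collapse = " "), "\n")
  cat("  overall:", if (isTRUE(ok$all_pass)) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Acceptance criteria for atmospheric model predictions
#'
#' Applies the published good-model criteria for atmospheric dispersion
#' and exposure models: mean bias within 30% of the mean (`0.7 < MG < 1.3`
#' and `|FB| < 0.3`), random scatter within a factor of two of the mean
#' (`VG < 1.6` and `NMSE < 4`), `FAC2 > 0.7`, and Pearson `r > 0.7`.
#'
#' @param report a `cabin_eval_report` (or any list with the six
#'   statistics).
#' @return named list of six booleans plus `all_pass`, their conjunction.
#'   An `NA` statistic yields `NA` for its criterion (and for `all_pass`
#'   unless another criterion already fails).
#' @export
criteria_check <- function(report) {
  checks <- list(
    MG = report$MG > 0.7 & report$MG < 1.3,
    FB = abs(report$FB) < 0.3,
    VG = report$VG < 1.6,
    NMSE = report$NMSE < 4,
    FAC2 = report$FAC2 > 0.7,
    r = report$r > 0.7)
  checks$all_pass <- Reduce(`&`, checks)
  checks
}

#' Fractional bias and the mean prediction ratio
#'
#' The fractional bias maps one-to-one onto the ratio of mean predicted to
#' mean observed concentration:
#' \deqn{\frac{\bar P}{\bar O} = \frac{1 - 0.5\,FB}{1 + 0.5\,FB}}
#' so e.g. FB = 0.67 corresponds to underprediction by a factor of two.
#' `ratio_to_fb` is the exact inverse, `FB = 2 (1 - ratio) / (1 + ratio)`.
#'
#' @param FB fractional bias, strictly inside (-2, 2).
#' @param ratio mean prediction ratio `mean(P)/mean(O)`, > 0.
#' @return the corresponding ratio (for `fb_to_ratio`) or fractional bias
#'   (for `ratio_to_fb`).
#' @export
#' @examples
#' fb_to_ratio(2 / 3)   # 0.5: underprediction by a factor of two
#' ratio_to_fb(0.5)     # 0.6667
fb_to_ratio <- function(FB) {
  if (any(FB <= -2 | FB >= 2))
    stop("FB = +/-2 corresponds to a zero mean; ratio undefined")
  (1 - 0.5 * FB) / (1 + 0.5 * FB)
}

#' @rdname fb_to_ratio
#' @export
ratio_to_fb <- function(ratio) {
  if (any(ratio <= 0)) stop("mean prediction ratio must be positive")
  2 * (1 - ratio) / (1 + ratio)
}
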