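#' Construct a plasma input function
#'
#' Wraps a vectorized function of time (hours post-injection) returning the
#' plasma activity concentration, tagging it with its unit and provenance.
#' Input functions drive the tumor compartments as a forcing term; they must
#' be non-negative for all `t >= 0`.
#'
#' @param f function of a numeric vector of times (h) returning concentrations.
#' @param unit `"pidg"` (%ID/g) or `"uM"`.
#' @param provenance `"analytic"` or `"measured-interpolated"`.
#' @return `f` with class `input_function` and attributes `unit`, `provenance`.
#' @export
input_function <- function(f, unit = c("pidg", "uM"),
                           provenance = c("analytic", "measured-interpolated")) {
  stopifnot(is.function(f))
  unit <- match.arg(unit)
  provenance <- match.arg(provenance)
  structure(f, class = c("input_function", "function"),
            unit = unit, provenance = provenance)
}

#' @export
print.input_function <- function(x, ...) {
  cat("Plasma input function [", attr(x, "unit"), ", ",
      attr(x, "provenance"), "]\n", sep = "")
  invisible(x)
}

#' Unit of an input function or TAC
#' @param x object with a unit attribute.
#' @return character scalar.
#' @export
input_unit <- function(x) attr(x, "unit")

# Convert an input function to uM, using an injection record when the
# function is in %ID/g.  Returns a plain closure (the unit bookkeeping is
# internal to simulation).
.input_as_uM <- function(input_fn, injection = NULL) {
  if (!inherits(input_fn, "input_function"))
    stop("'input_fn' must be an input_function", call. = FALSE)
  if (identical(attr(input_fn, "unit"), "uM")) return(input_fn)
  if (is.null(injection))
    stop("input function is in %ID/g; an injection_record is required ",
         "to convert it to molar units", call. = FALSE)
  function(t) pidg_to_molar(input_fn(t), injection)
}

#' Build an interpolated plasma input function from a measured TAC
#'
#' Piecewise-linear interpolation over the sampled range.  Beyond the last
#' sample the curve continues as the mono-exponential through the final two
#' points; before the first sample it is either back-extrapolated with the
#' mono-exponential rate fitted to the first two points
#' (`"monoexp_backfill"`, default) or held at the first value
#' (`"hold_first"`).
#'
#' @param plasma_tac a [tac()] object (blood/heart region, %ID/g).
#' @param injection optional [injection_record()]; required when
#'   `unit = "uM"`.
#' @param unit unit of the returned function: `"pidg"` (default) or `"uM"`.
#' @param pre_first_sample_policy extrapolation policy before the first
#'   sample time.
#' @param partition_factor scalar plasma/whole-blood partition factor applied
#'   multiplicatively to the measured values (default 1, i.e. the heart TAC is
#'   used directly as the plasma input).
#' @return an [input_function()] with provenance `"measured-interpolated"`.
#' @export
build_input_function <- function(plasma_tac, injection = NULL,
                                 unit = c("pidg", "uM"),
                                 pre_first_sample_policy = c("monoexp_backfill",
                                                             "hold_first"),
                                 partition_factor = 1) {
  unit <- match.arg(unit)
  pre_first_sample_policy <- match.arg(pre_first_sample_policy)
  stopifnot(inherits(plasma_tac, "tac"))
  tt <- plasma_tac$time_h
  yy <- plasma_tac$value_pidg * partition_factor
  if (length(tt) < 2L)
    stop("at least two plasma samples are required to build an input function",
         call. = FALSE)
  n <- length(tt)

  # mono-exponential tail through the last two points
  tail_rate <- if (yy[n] > 0 && yy[n - 1L] > 0) {
    log(yy[n - 1L] / yy[n]) / (tt[n] - tt[n - 1L])
  } else 0
  # back-extrapolation rate from the first two points
  head_rate <- if (yy[1L] > 0 && yy[2L] > 0) {
    log(yy[1L] / yy[2L]) / (tt[2L] - tt[1L])
  } else 0

  f_pidg <- function(t) {
    out <- numeric(length(t))
    mid <- t >= tt[1L] & t <= tt[n]
    if (any(mid)) out[mid] <- approx(tt, yy, xout = t[mid])$y
    lo <- t < tt[1L]
    if (any(lo)) {
      out[lo] <- if (pre_first_sample_policy == "hold_first") yy[1L]
                 else yy[1L] * exp(head_rate * (tt[1L] - t[lo]))
    }
    hi <- t > tt[n]
    if (any(hi)) out[hi] <- yy[n] * exp(-tail_rate * (t[hi] - tt[n]))
    pmax(out, 0)
  }
  f <- if (unit == "pidg") f_pidg else {
    if (is.null(injection))
      stop("unit = 'uM' requires an injection_record", call. = FALSE)
    function(t) pidg_to_molar(f_pidg(t), injection)
  }
  input_function(f, unit = unit, provenance = "measured-interpolated")
}
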