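#' Time-activity curve
#'
#' A sampled activity-concentration curve for one region of interest, in
#' percent injected dose per gram (%ID/g) versus hours post-injection.
#' Correction flags are carried explicitly: whether the values are decay
#' corrected to the time of injection and whether they are partial-volume
#' corrected.
#'
#' @param time_h sample times, h, strictly increasing, >= 0.
#' @param value_pidg activity concentrations, %ID/g, >= 0.
#' @param region region label (e.g. `"tumor"`, `"heart"`).
#' @param sd optional per-point uncertainty, %ID/g.
#' @param isotope optional [isotope()] reference.
#' @param decay_corrected_to_injection logical flag (default TRUE: PET TACs
#'   are conventionally reported decay corrected).
#' @param partial_volume_corrected logical flag (default FALSE).
#' @return object of class `tac`: a list with the fields above.
#' @export
tac <- function(time_h, value_pidg, region = "tumor", sd = NULL,
                isotope = NULL,
                decay_corrected_to_injection = TRUE,
                partial_volume_corrected = FALSE) {
  time_h <- as.numeric(time_h); value_pidg <- as.numeric(value_pidg)
  if (length(time_h) != length(value_pidg))
    stop("'time_h' and 'value_pidg' must have equal length", call. = FALSE)
  if (any(time_h < 0)) stop("sample times must be >= 0", call. = FALSE)
  bad <- which(diff(time_h) <= 0)
  if (length(bad))
    stop(sprintf("sample times must be strictly increasing; row %d (t = %g) is not after row %d (t = %g)",
                 bad[1L] + 1L, time_h[bad[1L] + 1L], bad[1L], time_h[bad[1L]]),
         call. = FALSE)
  neg <- which(value_pidg < 0)
  if (length(neg))
    stop(sprintf("activity values must be >= 0; row %d has value %g",
                 neg[1L], value_pidg[neg[1L]]), call. = FALSE)
  if (!is.null(sd) && length(sd) != length(time_h))
    stop("'sd' must match the number of samples", call. = FALSE)
  structure(list(time_h = time_h, value_pidg = value_pidg, region = region,
                 sd = sd, isotope = isotope,
                 decay_corrected_to_injection =
                   isTRUE(decay_corrected_to_injection),
                 partial_volume_corrected = isTRUE(partial_volume_corrected)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC [%s]: %d samples, %g-%g h, %.3g-%.3g %%ID/g\n",
              x$region, length(x$time_h), min(x$time_h), max(x$time_h),
              min(x$value_pidg), max(x$value_pidg)))
  cat(sprintf("  decay corrected: %s; PV corrected: %s\n",
              x$decay_corrected_to_injection, x$partial_volume_corrected))
  invisible(x)
}

#' Radioisotope reference
#'
#' @param name isotope name; known presets: 89Zr (t1/2 = 3.17 d), 124I
#'   (4.18 d), 131I, 177Lu, 111In, 64Cu.
#' @param half_life_h half-life in hours; required for unknown isotopes.
#' @return object of class `isotope` with fields `name`, `half_life_h` and
#'   decay constant `lambda_h` (= ln 2 / t1/2).
#' @examples
#' isotope("89Zr")$half_life_h  # 76.08
#' @export
isotope <- function(name, half_life_h = NULL) {
  if (is.null(half_life_h)) {
    half_life_h <- .known_isotopes[[name]]
    if (is.null(half_life_h))
      stop("unknown isotope '", name, "'; supply 'half_life_h'", call. = FALSE)
  }
  if (half_life_h <= 0) stop("half-life must be > 0", call. = FALSE)
  structure(list(name = name, half_life_h = half_life_h,
                 lambda_h = log(2) / half_life_h),
            class = "isotope")
}

#' Injection metadata
#'
#' Administered antibody mass and activity plus the quantities needed to
#' convert %ID/g to molar concentration.
#'
#' @param mass_ug administered antibody mass, micrograms (> 0).
#' @param activity_MBq administered activity, MBq (optional).
#' @param specific_activity_MBq_mg specific activity, MBq/mg (optional).
#' @param mw antibody molecular weight, g/mol (default 150,000 for intact
#'   IgG).
#' @param tumor_volume_mm3 tumor volume, mm^3 (optional; needed for partial
#'   volume correction).
#' @param density tissue density, g/mL (default 1.0, soft tissue).
#' @return object of class `injection_record`.
#' @export
injection_record <- function(mass_ug, activity_MBq = NULL,
                             specific_activity_MBq_mg = NULL,
                             mw = .MW_IGG, tumor_volume_mm3 = NULL,
                             density = 1.0) {
  if (mass_ug <= 0) stop("'mass_ug' must be > 0", call. = FALSE)
  if (mw <= 0) stop("'mw' must be > 0", call. = FALSE)
  if (density <= 0) stop("'density' must be > 0", call. = FALSE)
  if (!is.null(activity_MBq) && !is.null(specific_activity_MBq_mg)) {
    implied <- mass_ug / 1000 * specific_activity_MBq_mg
    if (abs(activity_MBq - implied) > 0.2 * max(activity_MBq, implied))
      stop(sprintf("inconsistent injection metadata: activity %.3g MBq vs mass x specific activity = %.3g MBq (>20%% apart)",
                   activity_MBq, implied), call. = FALSE)
  }
  structure(list(mass_ug = mass_ug, activity_MBq = activity_MBq,
                 specific_activity_MBq_mg = specific_activity_MBq_mg,
                 mw = mw, tumor_volume_mm3 = tumor_volume_mm3,
                 density = density),
            class = "injection_record")
}

#' Read and write time-activity curve files
#'
#' Delimited text (CSV) with header columns `time_h`, `value_pidg` and
#' optionally `sd`.  Unknown columns are preserved on round-trip.  Values are
#' written with 17 significant digits so that `read_tac(write_tac(x))`
#' reproduces the numbers bitwise.
#'
#' @param path file path.
#' @param region region label to attach (read) .
#' @param ... further arguments passed to [tac()] on read (flags, isotope).
#' @return `read_tac` returns a [tac()]; `write_tac` returns `path`
#'   invisibly.
#' @export
read_tac <- function(path, region = "tumor", ...) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("time_h", "value_pidg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("TAC file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- tac(df$time_h, df$value_pidg, region = region,
           sd = if ("sd" %in% names(df)) df$sd else NULL, ...)
  extra <- setdiff(names(df), c(need, "sd"))
  if (length(extra)) attr(x, "extra_columns") <- df[extra]
  x
}

#' @rdname read_tac
#' @param x a [tac()] object.
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac"))
  df <- data.frame(time_h = x$time_h, value_pidg = x$value_pidg)
  if (!is.null(x$sd)) df$sd <- x$sd
  extra <- attr(x, "extra_columns")
  if (!is.null(extra)) df <- cbind(df, extra)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Decay correction
#'
#' Corrects measured activity concentrations to the time of injection by
#' multiplying by `exp(+lambda t)` (`direction = "to_injection"`), or undoes
#' a prior correction by multiplying by `exp(-lambda t)`.  One half-life of
#' elapsed time doubles the corrected value.
#'
#' @param x a [tac()] object.
#' @param iso an [isotope()].
#' @param direction `"to_injection"` (default) or `"undo"`.
#' @return the corrected [tac()] with its flag updated.
#' @export
decay_correct <- function(x, iso, direction = c("to_injection", "undo")) {
  direction <- match.arg(direction)
  stopifnot(inherits(x, "tac"), inherits(iso, "isotope"))
  if (direction == "to_injection" && x$decay_corrected_to_injection)
    stop("TAC is already decay corrected to injection; refusing to correct twice",
         call. = FALSE)
  if (direction == "undo" && !x$decay_corrected_to_injection)
    stop("TAC is not decay corrected; nothing to undo", call. = FALSE)
  fac <- exp((if (direction == "to_injection") 1 else -1) *
               iso$lambda_h * x$time_h)
  x$value_pidg <- x$value_pidg * fac
  if (!is.null(x$sd)) x$sd <- x$sd * fac
  x$decay_corrected_to_injection <- direction == "to_injection"
  x$isotope <- iso
  x
}

#' Partial volume correction by recovery coefficient
#'
#' Divides TAC values by the recovery coefficient interpolated (piecewise
#' linearly) at the tumor's sphere-equivalent diameter.  The tumor is assumed
#' spherical: `d = (6 V / pi)^(1/3)`.  No extrapolation outside the table.
#'
#' @param x a [tac()] object.
#' @param tumor_volume_mm3 tumor volume, mm^3.
#' @param recovery_table data.frame with columns `diameter_mm` and
#'   `recovery` (coefficients in (0, 1]).
#' @return corrected [tac()] with `partial_volume_corrected = TRUE`.
#' @export
partial_volume_correct <- function(x, tumor_volume_mm3, recovery_table) {
  stopifnot(inherits(x, "tac"))
  if (x$partial_volume_corrected)
    stop("TAC is already partial-volume corrected", call. = FALSE)
  if (!all(c("diameter_mm", "recovery") %in% names(recovery_table)))
    stop("recovery_table needs columns 'diameter_mm' and 'recovery'",
         call. = FALSE)
  if (any(recovery_table$recovery <= 0 | recovery_table$recovery > 1))
    stop("recovery coefficients must lie in (0, 1]", call. = FALSE)
  d <- (6 * tumor_volume_mm3 / pi)^(1 / 3)
  rng <- range(recovery_table$diameter_mm)
  if (d < rng[1L] || d > rng[2L])
    stop(sprintf("sphere-equivalent diameter %.3g mm is outside the recovery table range [%.3g, %.3g]; no extrapolation",
                 d, rng[1L], rng[2L]), call. = FALSE)
  rc <- approx(recovery_table$diameter_mm, recovery_table$recovery,
               xout = d)$y
  x$value_pidg <- x$value_pidg / rc
  if (!is.null(x$sd)) x$sd <- x$sd / rc
  x$partial_volume_corrected <- TRUE
  x
}

#' Identity recovery table
#'
#' Default partial-volume recovery table with coefficient 1 everywhere (no
#' correction); scanner-specific coefficients should be supplied by the
#' user.
#' @param d_range diameter range covered, mm.
#' @return data.frame usable with [partial_volume_correct()].
#' @export
identity_recovery_table <- function(d_range = c(0.1, 100)) {
  message("using identity recovery table: no partial-volume correction applied")
  data.frame(diameter_mm = d_range, recovery = c(1, 1))
}
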