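#' Time integral of an activity curve
#'
#' Trapezoidal integral over a window.  A function is sampled densely
#' (`n_grid` points); a sampled curve (data.frame with `time`/`value` or
#' `time_h`/`value_pidg` columns) is integrated on its own grid, with the
#' window endpoints interpolated.
#'
#' @param curve function of time, or data.frame.
#' @param window `c(t0, t1)`, h.
#' @param n_grid number of samples for a functional curve (default 2001).
#' @return integral, in value-units x h (e.g. %ID/g x h).
#' @export
time_integral <- function(curve, window, n_grid = 2001L) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  if (is.function(curve)) {
    tt <- seq(window[1L], window[2L], length.out = n_grid)
    yy <- curve(tt)
  } else {
    df <- .as_curve_df(curve)
    if (window[1L] < min(df$time) - 1e-9 || window[2L] > max(df$time) + 1e-9)
      stop(sprintf("window [%g, %g] is outside the curve support [%g, %g]",
                   window[1L], window[2L], min(df$time), max(df$time)),
           call. = FALSE)
    tt <- sort(unique(c(window, df$time[df$time >= window[1L] &
                                          df$time <= window[2L]])))
    yy <- approx(df$time, df$value, xout = tt)$y
  }
  pracma::trapz(tt, yy)
}

.as_curve_df <- function(curve) {
  if (inherits(curve, "tac"))
    return(data.frame(time = curve$time_h, value = curve$value_pidg))
  if (is.data.frame(curve)) {
    tnm <- intersect(c("time", "time_h"), names(curve))[1L]
    vnm <- intersect(c("value", "value_pidg", "tumor_total_pidg"),
                     names(curve))[1L]
    if (is.na(tnm) || is.na(vnm))
      stop("curve data.frame needs time and value columns", call. = FALSE)
    return(data.frame(time = curve[[tnm]], value = curve[[vnm]]))
  }
  stop("unsupported curve type", call. = FALSE)
}

#' Targeting index
#'
#' Ratio of the time-integrated activity concentration in the tumor to that
#' in plasma over a window: a metric of tumor versus systemic exposure for
#' radioimmunotherapy planning.
#'
#' @param tumor_curve,plasma_curve functions of time or sampled curves (see
#'   [time_integral()]), same units.
#' @param window integration window `c(t0, t1)`, h.
#' @param model_variant optional label recorded in the result.
#' @return list of class `targeting_index_result` with the two integrals and
#'   their ratio.
#' @export
targeting_index <- function(tumor_curve, plasma_curve, window = c(0, 96),
                            model_variant = NA_character_) {
  ti_t <- time_integral(tumor_curve, window)
  ti_p <- time_integral(plasma_curve, window)
  if (ti_p <= 0)
    stop("plasma time integral is zero; targeting index undefined",
         call. = FALSE)
  structure(list(window = window, tumor_integral = ti_t,
                 plasma_integral = ti_p, index = ti_t / ti_p,
                 model_variant = model_variant),
            class = "targeting_index_result")
}

#' @export
print.targeting_index_result <- function(x, ...) {
  cat(sprintf("Targeting index over [%g, %g] h: %.3g (tumor %.4g / plasma %.4g)\n",
              x$window[1L], x$window[2L], x$index,
              x$tumor_integral, x$plasma_integral))
  invisible(x)
}

#' Predict targeting indices across antibody doses
#'
#' Forward-predicts tumor TACs at escalated antibody doses from parameters
#' estimated at a (typically low) tracer dose, and tabulates the targeting
#' index per dose.  Simulation is `state_driven` (no measured tumor data
#' exist at predicted doses).  By default all doses share one dose-normalized
#' plasma input shape in %ID/g (shape-invariant clearance), so the molar
#' plasma exposure scales proportionally with dose; per-dose inputs can be
#' supplied instead.
#'
#' @param fit a `fit_result` or a [kinetic_parameters()] object.
#' @param doses_ug antibody doses, micrograms, strictly increasing.
#' @param plasma_input an [input_function()] in %ID/g shared by all doses,
#'   or a list of such, one per dose.
#' @param window integration window, h (default `c(0, 96)`).
#' @param mw antibody molecular weight, g/mol.
#' @param n_grid dense simulation grid size (default 1001).
#' @param observed optional data.frame with columns `dose_ug`,
#'   `observed_index` and optionally `observed_se` for overlay.
#' @return data.frame of class `dose_response_table`: dose (ug, nmol),
#'   predicted targeting index, occupancy fraction at the end of the window
#'   (NA for the linear variant), and observed values when supplied.
#' @export
predict_dose_series <- function(fit, doses_ug, plasma_input,
                                window = c(0, 96), mw = .MW_IGG,
                                n_grid = 1001L, observed = NULL) {
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(diff(doses_ug) <= 0))
    stop("doses must be strictly increasing", call. = FALSE)
  inputs <- if (inherits(plasma_input, "input_function")) {
    rep(list(plasma_input), length(doses_ug))
  } else plasma_input
  if (length(inputs) != length(doses_ug))
    stop("supply one plasma input function per dose (or a single shared one)",
         call. = FALSE)
  for (i in seq_along(inputs))
    if (!inherits(inputs[[i]], "input_function") ||
        !identical(attr(inputs[[i]], "unit"), "pidg"))
      stop("missing or non-%ID/g input function for dose ", doses_ug[i],
           " ug", call. = FALSE)

  t_grid <- seq(window[1L], window[2L], length.out = n_grid)
  if (t_grid[1L] != 0) t_grid <- c(0, t_grid)
  rows <- lapply(seq_along(doses_ug), function(i) {
    inj <- injection_record(mass_ug = doses_ug[i], mw = mw)
    traj <- simulate_trajectory(params, inputs[[i]], t_grid,
                                occupancy_mode = "state_driven",
                                injection = inj)
    keep <- traj$time >= window[1L]
    ti <- targeting_index(
      data.frame(time = traj$time[keep], value = traj$tumor_total_pidg[keep]),
      data.frame(time = traj$time[keep], value = traj$plasma_pidg[keep]),
      window = window, model_variant = params$model_variant)
    occ_frac <- if (params$model_variant == "nonlinear") {
      traj$occupancy[nrow(traj)] / params$ag_total
    } else NA_real_
    data.frame(dose_ug = doses_ug[i],
               dose_nmol = mass_to_moles(doses_ug[i], mw),
               targeting_index = ti$index,
               occupancy_fraction_end = occ_frac)
  })
  out <- do.call(rbind, rows)
  if (!is.null(observed)) {
    m <- match(out$dose_ug, observed$dose_ug)
    out$observed_index <- observed$observed_index[m]
    if ("observed_se" %in% names(observed))
      out$observed_se <- observed$observed_se[m]
  }
  structure(out, class = c("dose_response_table", "data.frame"),
            model_variant = params$model_variant, window = window)
}

#' Decompose the tumor signal into surface, internalized and blood curves
#'
#' Splits the simulated total tumor signal into its surface-bound (`q2`),
#' internalized (`q3`) and blood-borne (`blood_fraction x plasma`)
#' components in %ID/g.  The three components sum to the total signal at
#' every grid point; the internalized component's peak time is reported.
#'
#' @param traj a `compartment_trajectory` simulated with an injection
#'   record (so %ID/g columns are available).
#' @return list of class `compartment_decomposition` with data.frames
#'   `surface`, `internalized`, `blood`, `total` (columns `time`, `value`)
#'   and `internalized_peak_h`.
#' @export
decompose_compartments <- function(traj) {
  stopifnot(inherits(traj, "compartment_trajectory"))
  inj <- attr(traj, "injection")
  if (is.null(inj))
    stop("trajectory lacks injection metadata; re-simulate with 'injection' ",
         "to obtain %ID/g curves", call. = FALSE)
  params <- attr(traj, "params")
  surf <- molar_to_pidg(traj$q2, inj)
  intern <- molar_to_pidg(traj$q3, inj)
  blood <- params$blood_fraction * traj$plasma_pidg
  cv <- function(v) data.frame(time = traj$time, value = v)
  structure(list(
    surface = cv(surf), internalized = cv(intern), blood = cv(blood),
    total = cv(traj$tumor_total_pidg),
    internalized_peak_h = traj$time[which.max(intern)]
  ), class = "compartment_decomposition")
}

#' Internalization flux in molecules per gram per hour
#'
#' The molecular rate of transfer from the cell surface into the cell:
#' `k_int * q2(t)` converted from uM/h to molecules g^-1 h^-1 via Avogadro's
#' number and the tissue density.
#'
#' @param traj a `compartment_trajectory` (molar states).
#' @param params [kinetic_parameters()] used for the simulation; defaults to
#'   the trajectory's own.
#' @param at `"max"` (default: scan the grid for the maximum flux) or a
#'   numeric time, h.
#' @param density tissue density, g/mL (default from the trajectory's
#'   injection record, else 1).
#' @return flux, molecules g^-1 h^-1.
#' @export
internalization_flux <- function(traj, params = attr(traj, "params"),
                                 at = "max", density = NULL) {
  stopifnot(inherits(traj, "compartment_trajectory"))
  if (is.null(density)) {
    inj <- attr(traj, "injection")
    density <- if (!is.null(inj)) inj$density else 1.0
  }
  q2 <- if (identical(at, "max")) {
    max(traj$q2)
  } else {
    approx(traj$time, traj$q2, xout = at)$y
  }
  flux_uM_h <- params$k_int * q2
  # uM/h = 1e-6 mol L^-1 h^-1 = 1e-9 mol mL^-1 h^-1; / density -> per gram
  flux_uM_h * 1e-9 / density * .AVOGADRO
}

#' Per-cell antigen turnover
#'
#' Converts a tissue-level internalization flux to a per-cell rate and to
#' the fraction of surface sites internalized per hour.
#'
#' @param flux internalization flux, molecules g^-1 h^-1.
#' @param cells_per_gram tumor cell density, cells/g.
#' @param sites_per_cell antigen sites per cell.
#' @return list with `molecules_per_cell_per_h` and
#'   `site_fraction_per_h`.
#' @examples
#' per_cell_turnover(1.2e13, 1e8, 6e5)
#' # 1.2e5 molecules/cell/h; 0.20 of sites per hour
#' @export
per_cell_turnover <- function(flux, cells_per_gram, sites_per_cell) {
  if (any(c(cells_per_gram, sites_per_cell) <= 0) || flux < 0)
    stop("inputs must be positive (flux >= 0)", call. = FALSE)
  per_cell <- flux / cells_per_gram
  list(molecules_per_cell_per_h = per_cell,
       site_fraction_per_h = per_cell / sites_per_cell)
}

#' Ratio of internalized activity between two trajectories
#'
#' `q3_a(t) / q3_b(t)` at a given time -- e.g. the residualizing versus
#' non-residualizing label contrast at the end of the imaging window.
#'
#' @param traj_a,traj_b `compartment_trajectory` objects whose grids contain
#'   `t`.
#' @param t time, h.
#' @return dimensionless ratio.
#' @export
internalized_ratio <- function(traj_a, traj_b, t) {
  q3a <- approx(traj_a$time, traj_a$q3, xout = t)$y
  q3b <- approx(traj_b$time, traj_b$q3, xout = t)$y
  if (is.na(q3a) || is.na(q3b))
    stop("t is outside a trajectory's grid", call. = FALSE)
  if (q3b == 0)
    stop("denominator trajectory has zero internalized activity at t",
         call. = FALSE)
  q3a / q3b
}
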