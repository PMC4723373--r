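#' Saturable binding rate
#'
#' The plasma-to-surface transfer rate of the model.  For the nonlinear
#' variant this is the bimolecular law
#' `k_a * max([Ag_total] - occupancy, 0) * [Ab]_plasma`; the available
#' antigen is clamped at zero so the rate can never be negative.  For the
#' linear comparator it is `k21_lin * [Ab]_plasma`, independent of occupancy.
#'
#' @param params [kinetic_parameters()].
#' @param plasma_conc plasma antibody concentration, M.
#' @param occupancy bound antigen-antibody complex concentration, M.
#' @return binding rate, M h^-1 (never negative).
#' @examples
#' p <- kinetic_parameters(k_a = 4.4e7, ag_total = 1.2, k_int = 0.2,
#'                         k_efflux = 0.01)
#' binding_rate(p, plasma_conc = 1e-7, occupancy = 0)  # 5.28e-6 M/h
#' @export
binding_rate <- function(params, plasma_conc, occupancy) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(plasma_conc < 0)) stop("'plasma_conc' must be >= 0", call. = FALSE)
  if (any(occupancy < 0)) stop("'occupancy' must be >= 0", call. = FALSE)
  if (params$model_variant == "nonlinear") {
    free_ag <- pmax(params$ag_total * 1e-6 - occupancy, 0)  # uM -> M
    params$k_a * free_ag * plasma_conc
  } else {
    params$k21_lin * plasma_conc
  }
}

#' Right-hand side of the tumor compartment ODE system
#'
#' Two states (uM): `q2`, antibody bound at the cell surface, and `q3`,
#' internalized antibody.  Plasma is a forcing function, not a solved state.
#' `dq2/dt = binding - k_int * q2`; `dq3/dt = k_int * q2 - k_efflux * q3`.
#' All transfers are unidirectional: no dissociation from the surface, no
#' recycling of internalized complex.
#'
#' The occupancy entering the binding term is `q2 + q3` in `"state_driven"`
#' mode, or an externally supplied occupancy curve (derived from a measured
#' tumor TAC) in `"data_driven"` mode.
#'
#' @param t time, h.
#' @param state numeric `c(q2, q3)`, uM.
#' @param params [kinetic_parameters()].
#' @param input_fn plasma input in uM: an [input_function()] with unit
#'   `"uM"`, or any function of t returning uM.
#' @param occupancy_mode `"state_driven"` or `"data_driven"`.
#' @param occupancy_fn function of t returning occupied antigen (uM);
#'   required in `"data_driven"` mode.
#' @return derivative vector `c(dq2, dq3)`, uM h^-1.
#' @export
ode_rhs <- function(t, state, params, input_fn,
                    occupancy_mode = c("state_driven", "data_driven"),
                    occupancy_fn = NULL) {
  occupancy_mode <- match.arg(occupancy_mode)
  if (occupancy_mode == "data_driven" && is.null(occupancy_fn))
    stop("data_driven mode requires an occupancy function derived from ",
         "a measured tumor TAC", call. = FALSE)
  q2 <- state[[1L]]; q3 <- state[[2L]]
  plasma_uM <- input_fn(t)
  occ_uM <- if (occupancy_mode == "state_driven") q2 + q3 else occupancy_fn(t)
  # binding law evaluated in M, returned in M/h; system runs in uM
  b_uM <- binding_rate(params, plasma_uM * 1e-6, max(occ_uM, 0) * 1e-6) * 1e6
  c(b_uM - params$k_int * q2,
    params$k_int * q2 - params$k_efflux * q3)
}

#' ODE solver configuration
#'
#' @param method `"lsoda"` (adaptive, stiff-capable; default) or `"euler"`
#'   (explicit fixed step, retained as an independent cross-check route).
#' @param rtol relative tolerance (lsoda). Default 1e-8.
#' @param atol absolute tolerance, uM (lsoda). Default 1e-12.
#' @param dt fixed step, h (euler). Default 0.001.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(method = c("lsoda", "euler"),
                          rtol = 1e-8, atol = 1e-12, dt = 0.001) {
  method <- match.arg(method)
  structure(list(method = method, rtol = rtol, atol = atol, dt = dt),
            class = "solver_config")
}

#' Simulate tumor compartment trajectories
#'
#' Integrates the two-compartment tumor system from `q2 = q3 = 0` at
#' injection under a plasma forcing function, and reconstructs the total
#' tumor signal `q2 + q3 + blood_fraction * plasma`.
#'
#' @param params [kinetic_parameters()].
#' @param input_fn [input_function()]; if in %ID/g, `injection` is required
#'   for conversion to uM.
#' @param t_grid strictly increasing time grid starting at 0, h.
#' @param occupancy_mode `"state_driven"` (default; required for forward
#'   prediction) or `"data_driven"` (occupancy taken from a measured tumor
#'   TAC, the convention used during fitting).
#' @param occupancy_fn occupancy curve (uM) for `"data_driven"` mode.
#' @param injection optional [injection_record()]; when supplied the
#'   trajectory also carries %ID/g columns.
#' @param solver [solver_config()].
#' @return A `compartment_trajectory`: a data.frame with columns `time`,
#'   `q2`, `q3`, `occupancy`, `plasma_uM`, `tumor_total_uM` and, when an
#'   injection record is available, `plasma_pidg`, `tumor_total_pidg`;
#'   attributes carry the parameters and injection metadata.
#' @export
simulate_trajectory <- function(params, input_fn, t_grid,
                                occupancy_mode = c("state_driven",
                                                   "data_driven"),
                                occupancy_fn = NULL,
                                injection = NULL,
                                solver = solver_config()) {
  occupancy_mode <- match.arg(occupancy_mode)
  stopifnot(inherits(params, "kinetic_parameters"))
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0) || t_grid[1L] != 0)
    stop("'t_grid' must be strictly increasing and start at 0", call. = FALSE)
  if (occupancy_mode == "data_driven" && is.null(occupancy_fn))
    stop("data_driven mode requires an occupancy function", call. = FALSE)
  f_uM <- .input_as_uM(input_fn, injection)

  if (solver$method == "lsoda") {
    deriv <- function(t, y, parms) {
      list(ode_rhs(t, y, params, f_uM, occupancy_mode, occupancy_fn))
    }
    sol <- deSolve::lsoda(y = c(q2 = 0, q3 = 0), times = t_grid, func = deriv,
                          parms = NULL, rtol = solver$rtol, atol = solver$atol)
    diagn <- attributes(sol)$istate
    if (!is.null(diagn) && diagn[1L] < 0)
      stop("ODE solver failed (lsoda istate = ", diagn[1L], "); ",
           "check parameter magnitudes and input function", call. = FALSE)
    sol <- as.data.frame(sol)
    if (anyNA(sol$q2) || anyNA(sol$q3))
      stop("ODE solver returned NaN/NA states; integration did not converge",
           call. = FALSE)
    q2 <- sol$q2; q3 <- sol$q3
  } else {
    eul <- .euler_solve(params, f_uM, t_grid, occupancy_mode, occupancy_fn,
                        dt = solver$dt)
    q2 <- eul$q2; q3 <- eul$q3
  }
  q2 <- pmax(q2, 0); q3 <- pmax(q3, 0)
  plasma_uM <- f_uM(t_grid)
  traj <- data.frame(
    time = t_grid, q2 = q2, q3 = q3,
    occupancy = q2 + q3,
    plasma_uM = plasma_uM,
    tumor_total_uM = q2 + q3 + params$blood_fraction * plasma_uM
  )
  if (!is.null(injection)) {
    traj$plasma_pidg <- molar_to_pidg(traj$plasma_uM, injection)
    traj$tumor_total_pidg <- molar_to_pidg(traj$tumor_total_uM, injection)
  }
  structure(traj,
            class = c("compartment_trajectory", "data.frame"),
            params = params, injection = injection,
            occupancy_mode = occupancy_mode)
}

# explicit fixed-step Euler, interpolated onto t_grid
.euler_solve <- function(params, f_uM, t_grid, occupancy_mode, occupancy_fn,
                         dt) {
  t_end <- t_grid[length(t_grid)]
  n <- ceiling(t_end / dt)
  tt <- seq(0, by = dt, length.out = n + 1L)
  q2 <- q3 <- numeric(n + 1L)
  y <- c(0, 0)
  for (i in seq_len(n)) {
    d <- ode_rhs(tt[i], y, params, f_uM, occupancy_mode, occupancy_fn)
    y <- y + dt * d
    y <- pmax(y, 0)
    q2[i + 1L] <- y[1L]; q3[i + 1L] <- y[2L]
  }
  list(q2 = approx(tt, q2, xout = t_grid)$y,
       q3 = approx(tt, q3, xout = t_grid)$y)
}

#' @export
print.compartment_trajectory <- function(x, ...) {
  cat("Compartment trajectory:", nrow(x), "time points over [",
      x$time[1L], ",", x$time[nrow(x)], "] h\n")
  cat(sprintf("  peak tumor total: %.4g uM at %.3g h\n",
              max(x$tumor_total_uM), x$time[which.max(x$tumor_total_uM)]))
  invisible(x)
}

#' Closed-form solution of the linear two-stage cascade with constant input
#'
#' Exact solution of `q2' = c - k_int q2`, `q3' = k_int q2 - k_efflux q3`
#' from zero initial conditions, where `c = k21_lin * constant_input`.
#' Serves as an independent analytic cross-check of the ODE solver in the
#' linear limit of the model.
#'
#' @param k21_lin,k_int,k_efflux rates, h^-1 (all >= 0).
#' @param constant_input constant plasma concentration, uM.
#' @param t time(s), h.
#' @return list with vectors `q2`, `q3` (uM).
#' @export
analytic_linear_solution <- function(k21_lin, k_int, k_efflux,
                                     constant_input, t) {
  stopifnot(k21_lin >= 0, k_int >= 0, k_efflux >= 0, constant_input >= 0,
            all(t >= 0))
  cc <- k21_lin * constant_input
  k2 <- k_int; k3 <- k_efflux
  q2 <- if (k2 > 0) cc / k2 * (1 - exp(-k2 * t)) else cc * t
  if (k2 == 0) {
    q3 <- rep(0, length(t))
  } else if (k3 == 0) {
    q3 <- cc * t - cc / k2 * (1 - exp(-k2 * t))
  } else if (abs(k3 - k2) < 1e-10 * max(k2, k3)) {
    # equal-rate limit
    q3 <- cc / k2 * (1 - exp(-k2 * t)) - cc * t * exp(-k2 * t)
  } else {
    q3 <- cc / k3 * (1 - exp(-k3 * t)) -
      cc * (exp(-k2 * t) - exp(-k3 * t)) / (k3 - k2)
  }
  list(q2 = q2, q3 = q3)
}
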