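#' Poisson-style fitting weights
#'
#' Weights for the weighted least-squares objective under the assumption
#' that the measurement variance is proportional to the signal (counting
#' statistics): `w_i = 1 / max(y_i, floor)`.  The floor keeps weights finite
#' for near-zero samples.
#'
#' @param values observed activity concentrations, %ID/g.
#' @param floor minimum value entering the denominator, %ID/g (default
#'   0.01).
#' @return numeric weights.
#' @export
poisson_weights <- function(values, floor = 0.01) {
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  1 / pmax(values, floor)
}

#' In vitro binding priors
#'
#' Cell-level antigen density and affinity from saturation binding assays,
#' used to derive starting values for the kinetic fit.
#'
#' @param b_max_sites_per_cell antigen sites per cell (default 600,000; the
#'   assay range for LNCaP/PSMA is 600,000-800,000).
#' @param k_d_nM equilibrium dissociation constant, nM (default 1.83).
#' @param cells_per_gram tumor cell density, cells per gram (default 1e8).
#' @return list of class `in_vitro_priors`.
#' @export
in_vitro_priors <- function(b_max_sites_per_cell = 6e5, k_d_nM = 1.83,
                            cells_per_gram = 1e8) {
  if (b_max_sites_per_cell <= 0 || k_d_nM <= 0 || cells_per_gram <= 0)
    stop("priors must be positive", call. = FALSE)
  structure(list(b_max_sites_per_cell = b_max_sites_per_cell,
                 k_d_nM = k_d_nM, cells_per_gram = cells_per_gram),
            class = "in_vitro_priors")
}

#' Starting parameter values from in vitro priors
#'
#' The antigen-pool start is the in vitro site density scaled to tissue
#' concentration: `ag_total0 = B_max * cells_per_gram / N_A * 1e9` uM
#' (density 1 g/mL).  Rate starts come from configured priors.
#'
#' @param priors [in_vitro_priors()].
#' @param injection optional [injection_record()] (density used if given).
#' @param k_a_prior association-rate starting value, M^-1 h^-1.
#' @param k_int0,k_efflux0 first-order rate starting values, h^-1.
#' @param blood_fraction fixed tumor blood fraction.
#' @return [kinetic_parameters()] (nonlinear variant).
#' @examples
#' initial_params(in_vitro_priors(cells_per_gram = 1e9))$ag_total  # ~1.0 uM
#' @export
initial_params <- function(priors = in_vitro_priors(), injection = NULL,
                           k_a_prior = 1e6, k_int0 = 0.1, k_efflux0 = 0.1,
                           blood_fraction = 0.08) {
  stopifnot(inherits(priors, "in_vitro_priors"))
  density <- if (!is.null(injection)) injection$density else 1.0
  ag0 <- priors$b_max_sites_per_cell * priors$cells_per_gram /
    .AVOGADRO * density * 1e9
  kinetic_parameters(k_a = k_a_prior, ag_total = ag0,
                     k_int = k_int0, k_efflux = k_efflux0,
                     blood_fraction = blood_fraction)
}

#' Default fitting bounds
#'
#' Box bounds bracketing physiologically plausible values by at least two
#' orders of magnitude on each side.
#' @param model_variant `"nonlinear"` or `"linear"`.
#' @return named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function(model_variant = c("nonlinear", "linear")) {
  model_variant <- match.arg(model_variant)
  if (model_variant == "nonlinear") {
    list(k_a = c(1e5, 1e10), ag_total = c(1e-3, 1e2),
         k_int = c(1e-4, 1e2), k_efflux = c(1e-4, 1e2))
  } else {
    list(k21_lin = c(1e-6, 1e2),
         k_int = c(1e-4, 1e2), k_efflux = c(1e-4, 1e2))
  }
}

#' Fitting configuration
#'
#' @param model_variant `"nonlinear"` (default) or `"linear"` comparator.
#' @param weighting `"poisson"` (default, w = 1/y), `"uniform"`, or
#'   `"user_sd"` (w = 1/sd^2 from the TAC).
#' @param weight_floor floor for Poisson weights, %ID/g.
#' @param multistart number of optimizer starts (default 16): the first is
#'   the prior-derived start, the rest a seeded Latin hypercube over the
#'   (log) bounds.
#' @param seed integer seed for the multistart draw.
#' @param bounds named list of bounds; default [default_bounds()].
#' @param occupancy_mode occupancy convention inside the binding term during
#'   fitting: `"data_driven"` (default; occupancy interpolated from the
#'   measured tumor TAC) or `"state_driven"` (occupancy = q2 + q3).
#' @param blood_fraction fixed tumor blood fraction (default 0.08).
#' @param priors [in_vitro_priors()] for the first start.
#' @param k_a_prior,k_int0,k_efflux0 starting rates for the first start.
#' @param solver [solver_config()] used inside the objective.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @param branch_preference `"k_int_ge_k_efflux"` (default) resolves the
#'   internalization/efflux exchange ambiguity of the cascade toward the
#'   branch with internalization at least as fast as efflux; `"none"`
#'   selects purely by objective.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(model_variant = c("nonlinear", "linear"),
                       weighting = c("poisson", "uniform", "user_sd"),
                       weight_floor = 0.01,
                       multistart = 16, seed = 1,
                       bounds = NULL,
                       occupancy_mode = c("data_driven", "state_driven"),
                       blood_fraction = 0.08,
                       priors = in_vitro_priors(),
                       k_a_prior = 1e6, k_int0 = 0.1, k_efflux0 = 0.1,
                       solver = solver_config(),
                       maxiter = 200,
                       branch_preference = c("k_int_ge_k_efflux", "none")) {
  model_variant <- match.arg(model_variant)
  weighting <- match.arg(weighting)
  occupancy_mode <- match.arg(occupancy_mode)
  branch_preference <- match.arg(branch_preference)
  if (is.null(bounds)) bounds <- default_bounds(model_variant)
  structure(list(model_variant = model_variant, weighting = weighting,
                 weight_floor = weight_floor, multistart = multistart,
                 seed = seed, bounds = bounds,
                 occupancy_mode = occupancy_mode,
                 blood_fraction = blood_fraction, priors = priors,
                 k_a_prior = k_a_prior, k_int0 = k_int0,
                 k_efflux0 = k_efflux0, solver = solver, maxiter = maxiter,
                 branch_preference = branch_preference),
            class = "fit_config")
}

# assemble a kinetic_parameters object from a log10 parameter vector
.theta_to_params <- function(theta, variant, blood_fraction) {
  v <- 10^theta
  if (variant == "nonlinear") {
    kinetic_parameters(k_a = v[[1L]], ag_total = v[[2L]],
                       k_int = v[[3L]], k_efflux = v[[4L]],
                       blood_fraction = blood_fraction)
  } else {
    kinetic_parameters(k21_lin = v[[1L]], k_int = v[[2L]], k_efflux = v[[3L]],
                       blood_fraction = blood_fraction,
                       model_variant = "linear")
  }
}

#' Fit the compartment model to a tumor time-activity curve
#'
#' Estimates the model's free parameters (nonlinear variant: `k_a`,
#' `ag_total`, `k_int`, `k_efflux`; linear comparator: `k21_lin`, `k_int`,
#' `k_efflux`) by weighted non-linear least squares on the tumor %ID/g
#' samples, using bounded Levenberg-Marquardt in log10 parameter space with
#' a seeded Latin-hypercube multistart.  The blood fraction is held fixed.
#'
#' @param tumor_tac [tac()] for the tumor region (>= 5 samples).
#' @param plasma either a [tac()] for the blood/heart region (interpolated
#'   via [build_input_function()]) or an [input_function()] directly.
#' @param injection [injection_record()] for %ID/g <-> molar conversion.
#' @param cfg [fit_config()].
#' @return object of class `fit_result`: estimated parameters, asymptotic
#'   standard errors, weighted residuals, unweighted RMSE (%ID/g),
#'   objective value and trace, per-start diagnostics, and a dense fitted
#'   tumor TAC.
#' @export
fit_kinetics <- function(tumor_tac, plasma, injection, cfg = fit_config()) {
  stopifnot(inherits(tumor_tac, "tac"), inherits(injection, "injection_record"))
  times <- tumor_tac$time_h
  obs <- tumor_tac$value_pidg
  if (length(times) < 5L)
    stop("at least 5 tumor time points are required", call. = FALSE)

  input_pidg <- if (inherits(plasma, "tac")) {
    build_input_function(plasma, unit = "pidg")
  } else if (inherits(plasma, "input_function")) {
    if (identical(attr(plasma, "unit"), "pidg")) plasma
    else input_function(function(t) molar_to_pidg(plasma(t), injection),
                        unit = "pidg", provenance = attr(plasma, "provenance"))
  } else stop("'plasma' must be a tac or an input_function", call. = FALSE)
  input_uM <- input_function(function(t) pidg_to_molar(input_pidg(t), injection),
                             unit = "uM",
                             provenance = attr(input_pidg, "provenance"))

  w <- switch(cfg$weighting,
    poisson = poisson_weights(obs, cfg$weight_floor),
    uniform = rep(1, length(obs)),
    user_sd = {
      if (is.null(tumor_tac$sd))
        stop("weighting = 'user_sd' requires per-point sd in the tumor TAC",
             call. = FALSE)
      1 / tumor_tac$sd^2
    })
  sw <- sqrt(w)

  # occupancy derived from the measured tumor activity (blood-subtracted),
  # anchored at zero occupancy at injection
  occupancy_fn <- NULL
  if (cfg$occupancy_mode == "data_driven") {
    occ_pidg <- pmax(obs - cfg$blood_fraction * input_pidg(times), 0)
    occ_uM <- pidg_to_molar(occ_pidg, injection)
    occupancy_fn <- approxfun(c(0, times), c(0, occ_uM), rule = 2)
  }

  t_grid <- sort(unique(c(0, times)))
  idx <- match(times, t_grid)

  # fast objective: compiled RHS with tabulated forcings (see
  # simulate-compiled.R); the reported fit uses the exact closure-based path
  plasma_tab <- .tabulate_input(input_uM, max(times))
  occ_tab <- if (cfg$occupancy_mode == "data_driven") {
    occ_pidg <- pmax(obs - cfg$blood_fraction * input_pidg(times), 0)
    cbind(c(0, times), c(0, pidg_to_molar(occ_pidg, injection)))
  }
  plasma_uM_obs <- input_uM(times)
  penalty <- sqrt(mean(obs^2)) * 1e3
  model_pidg_fast <- function(params) {
    sol <- .simulate_compiled(params, t_grid, plasma_tab, occ_tab,
                              rtol = cfg$solver$rtol, atol = cfg$solver$atol)
    if (!sol$ok) return(NULL)
    molar_to_pidg(sol$q2[idx] + sol$q3[idx] +
                    params$blood_fraction * plasma_uM_obs, injection)
  }
  resid_fn <- function(theta) {
    p <- .theta_to_params(theta, cfg$model_variant, cfg$blood_fraction)
    m <- model_pidg_fast(p)
    if (is.null(m)) return(sw * penalty)  # solver failure: repel optimizer
    sw * (m - obs)
  }
  model_pidg <- function(params) {
    traj <- simulate_trajectory(params, input_uM, t_grid,
                                occupancy_mode = cfg$occupancy_mode,
                                occupancy_fn = occupancy_fn,
                                injection = injection, solver = cfg$solver)
    traj$tumor_total_pidg[idx]
  }

  bounds <- cfg$bounds
  p_names <- names(bounds)
  lower <- log10(vapply(bounds, `[`, numeric(1L), 1L))
  upper <- log10(vapply(bounds, `[`, numeric(1L), 2L))

  # start 1: prior-derived; remaining: Latin hypercube over log bounds
  p0 <- initial_params(cfg$priors, injection, k_a_prior = cfg$k_a_prior,
                       k_int0 = cfg$k_int0, k_efflux0 = cfg$k_efflux0,
                       blood_fraction = cfg$blood_fraction)
  th0 <- if (cfg$model_variant == "nonlinear") {
    log10(c(p0$k_a, p0$ag_total, p0$k_int, p0$k_efflux))
  } else {
    log10(c(p0$k_a * p0$ag_total * 1e-6, p0$k_int, p0$k_efflux))
  }
  th0 <- pmin(pmax(th0, lower), upper)
  starts <- list(th0)
  if (cfg$multistart > 1L) {
    set.seed(cfg$seed)
    u <- lhs::randomLHS(cfg$multistart - 1L, length(lower))
    for (i in seq_len(nrow(u)))
      starts[[i + 1L]] <- lower + u[i, ] * (upper - lower)
  }

  runs <- lapply(seq_along(starts), function(i) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$maxiter, maxfev = 10000L,
                           # finite-difference step must exceed ODE solver
                           # noise or the Jacobian degenerates
                           epsfcn = 1e-6)),
      error = function(e) e)
    list(start = i, fit = out)
  })
  # polish the k_int/k_efflux-swapped twin of the provisional best: the
  # exchange degeneracy of the cascade means the mirrored solution can fit
  # equally well, and explicit polishing guarantees both branches are
  # represented before selection
  ok0 <- vapply(runs, function(r) !inherits(r$fit, "error"), logical(1L))
  if (any(ok0) && cfg$model_variant == "nonlinear") {
    devs <- vapply(runs, function(r)
      if (inherits(r$fit, "error")) Inf else r$fit$deviance, numeric(1L))
    tw <- runs[[which.min(devs)]]$fit$par
    tw[3:4] <- tw[4:3]
    tw <- pmin(pmax(tw, lower), upper)
    twin <- tryCatch(
      minpack.lm::nls.lm(par = tw, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$maxiter, maxfev = 10000L,
                           epsfcn = 1e-6)),
      error = function(e) e)
    runs[[length(runs) + 1L]] <- list(start = length(runs) + 1L, fit = twin)
  }

  ok <- vapply(runs, function(r) !inherits(r$fit, "error"), logical(1L))
  per_start <- data.frame(
    start = seq_along(runs),
    objective = vapply(runs, function(r)
      if (inherits(r$fit, "error")) NA_real_ else r$fit$deviance, numeric(1L)),
    message = vapply(runs, function(r)
      if (inherits(r$fit, "error")) conditionMessage(r$fit)
      else r$fit$message, character(1L))
  )
  if (!any(ok))
    stop("all optimizer starts failed:\n",
         paste(sprintf("  start %d: %s", per_start$start, per_start$message),
               collapse = "\n"), call. = FALSE)

  # Selection among optima that the data cannot distinguish.  The total
  # tumor signal of the two-stage cascade is symmetric under swapping k_int
  # and k_efflux in the unsaturated regime, and k_int is unidentifiable
  # upward when binding is rate-limiting, so multistart routinely lands on
  # several near-equivalent optima.  A candidate set is formed by a
  # likelihood-ratio criterion (weighted SSE not significantly worse than
  # the best at the 95% level); within it the preference is (1) the branch
  # with internalization at least as fast as efflux -- the configuration
  # the in vitro data support for an internalizing antigen -- and (2) the
  # solution closest (log scale) to the in-vitro-derived start.
  obj_min <- min(per_start$objective, na.rm = TRUE)
  n_obs <- length(obs); n_par <- length(lower)
  lr_window <- if (n_obs > n_par) {
    1 + stats::qchisq(0.95, n_par) / (n_obs - n_par)
  } else 1.01
  cand <- which(!is.na(per_start$objective) &
                  per_start$objective <= obj_min * lr_window + 1e-12)
  branch_ok <- vapply(cand, function(i) {
    kp <- .theta_to_params(runs[[i]]$fit$par, cfg$model_variant,
                           cfg$blood_fraction)
    kp$k_int >= kp$k_efflux
  }, logical(1L))
  if (identical(cfg$branch_preference, "none")) branch_ok[] <- FALSE
  if (any(branch_ok)) cand <- cand[branch_ok]
  d0 <- vapply(cand, function(i) sum((runs[[i]]$fit$par - th0)^2), numeric(1L))
  best <- runs[[cand[which.min(d0)]]]$fit
  theta_hat <- best$par
  params_hat <- .theta_to_params(theta_hat, cfg$model_variant,
                                 cfg$blood_fraction)

  est <- 10^theta_hat
  names(est) <- p_names
  at_bound <- (theta_hat - lower < 1e-3) | (upper - theta_hat < 1e-3)
  if (any(at_bound))
    warning("parameter(s) at bound: ", paste(p_names[at_bound], collapse = ", "),
            call. = FALSE)

  n <- length(obs); p <- length(theta_hat)
  s2 <- best$deviance / max(n - p, 1L)
  se <- rep(NA_real_, p)
  cov_log <- tryCatch(2 * s2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov_log) && all(diag(cov_log) >= 0))
    se <- sqrt(diag(cov_log)) * log(10) * est  # delta method, log10 -> natural
  names(se) <- p_names

  model_hat <- model_pidg(params_hat)
  dense_grid <- seq(0, max(times), length.out = 401L)
  dense <- simulate_trajectory(params_hat, input_uM, dense_grid,
                               occupancy_mode = cfg$occupancy_mode,
                               occupancy_fn = occupancy_fn,
                               injection = injection, solver = cfg$solver)

  structure(list(
    params = params_hat,
    estimates = est,
    se = se,
    weighted_residuals = sw * (model_hat - obs),
    observed_pidg = obs,
    model_at_obs = model_hat,
    times = times,
    rmse = sqrt(mean((model_hat - obs)^2)),
    objective = best$deviance,
    convergence = list(message = best$message, niter = best$niter,
                       rsstrace = best$rsstrace, at_bound = at_bound,
                       per_start = per_start),
    fitted_tac = data.frame(time_h = dense_grid,
                            value_pidg = dense$tumor_total_pidg),
    cfg = cfg, injection = injection
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Compartmental fit (", x$cfg$model_variant, " variant)\n", sep = "")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    se = signif(x$se, 3))
  print(tab)
  cat(sprintf("RMSE: %.3g %%ID/g; objective: %.4g; %s\n",
              x$rmse, x$objective, x$convergence$message))
  invisible(x)
}

#' Root-mean-squared error of a fit
#'
#' Unweighted root-mean-square of (model - observed) at the sample times,
#' in %ID/g -- the goodness-of-fit summary reported per animal.
#'
#' @param fit a `fit_result`.
#' @return RMSE, %ID/g.
#' @export
rmse <- function(fit) {
  stopifnot(!is.null(fit$model_at_obs), !is.null(fit$observed_pidg))
  sqrt(mean((fit$model_at_obs - fit$observed_pidg)^2))
}

#' Descriptive group comparison of a fitted parameter
#'
#' Mean +/- SD per group and a Welch two-sample t-test, e.g. for contrasting
#' the efflux rate between residualizing and non-residualizing labels.
#' Reported descriptively; per-animal fits are not pooled into a joint model.
#'
#' @param fits_a,fits_b lists of `fit_result` objects.
#' @param param parameter name (default `"k_efflux"`).
#' @return list with group summaries, the fold difference of means, and the
#'   `htest` object.
#' @export
compare_groups <- function(fits_a, fits_b, param = "k_efflux") {
  va <- vapply(fits_a, function(f) f$estimates[[param]], numeric(1L))
  vb <- vapply(fits_b, function(f) f$estimates[[param]], numeric(1L))
  list(mean_a = mean(va), sd_a = sd(va),
       mean_b = mean(vb), sd_b = sd(vb),
       fold = mean(va) / mean(vb),
       welch = t.test(va, vb))
}
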