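# Fast ODE path for the fitting loop: compiled right-hand side with
# tabulated (piecewise-linear) forcing functions.  The user-facing
# simulate_trajectory() evaluates the input function exactly through an R
# closure; this path trades exact forcing evaluation for speed and is used
# only inside objective functions.  Equivalence of the two routes is
# covered by the test suite.
.simulate_compiled <- function(params, t_grid, plasma_tab, occ_tab = NULL,
                               rtol = 1e-8, atol = 1e-12, maxsteps = 10000L) {
  linear <- params$model_variant == "linear"
  p <- c(if (linear) params$k21_lin else params$k_a * 1e-6,  # uM^-1 h^-1
         if (linear) 0 else params$ag_total,
         params$k_int, params$k_efflux,
         as.numeric(linear),
         as.numeric(!is.null(occ_tab)))
  if (is.null(occ_tab))
    occ_tab <- cbind(range(t_grid), c(0, 0))
  sol <- suppressWarnings(deSolve::lsoda(
    y = c(0, 0), times = t_grid, func = "ik_derivs", parms = p,
    dllname = "immunokin", initfunc = "ik_initmod", initforc = "ik_initforc",
    forcings = list(plasma_tab, occ_tab),
    fcontrol = list(method = "linear", rule = 2),
    rtol = rtol, atol = atol, maxsteps = maxsteps))
  list(q2 = pmax(sol[, 2L], 0), q3 = pmax(sol[, 3L], 0),
       ok = !anyNA(sol[, 2L]) && !anyNA(sol[, 3L]) &&
         nrow(sol) == length(t_grid))
}

# tabulate a (uM) input closure for use as a forcing table
.tabulate_input <- function(f_uM, t_max, dt = 0.05) {
  tt <- unique(c(seq(0, t_max, by = dt), t_max))
  cbind(tt, f_uM(tt))
}
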