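test_that("saturable binding law matches hand arithmetic and shuts off at saturation", {
  p <- kinetic_parameters(k_a = 4.4e7, ag_total = 1.2, k_int = 0.2,
                          k_efflux = 0.01)
  # 4.4e7 * 1.2e-6 * 1e-7 M/h
  expect_equal(binding_rate(p, plasma_conc = 1e-7, occupancy = 0), 5.28e-6)
  # saturation: no free antigen, no binding
  expect_equal(binding_rate(p, plasma_conc = 1e-6, occupancy = 1.2e-6), 0)
  # occupancy beyond the pool is clamped, never a negative rate
  expect_equal(binding_rate(p, plasma_conc = 1e-6, occupancy = 2e-6), 0)
  # no ligand, no binding
  expect_equal(binding_rate(p, plasma_conc = 0, occupancy = 5e-7), 0)
  expect_error(binding_rate(p, plasma_conc = -1e-7, occupancy = 0), ">= 0")
  expect_error(binding_rate(p, plasma_conc = 1e-7, occupancy = -1), ">= 0")

  pl <- kinetic_parameters(k21_lin = 0.25, k_int = 0.2, k_efflux = 0.01,
                           model_variant = "linear")
  expect_equal(binding_rate(pl, plasma_conc = 2e-7, occupancy = 1e-6),
               0.25 * 2e-7)
})

test_that("ODE right-hand side implements the unidirectional cascade", {
  inp <- constant_input_uM(0.5)
  p <- kinetic_parameters(k_a = 1e6, ag_total = 1.2, k_int = 0, k_efflux = 0)
  d <- ode_rhs(1, c(0.1, 0.05), p, inp)
  expect_gt(d[1L], 0)   # uptake only
  expect_equal(d[2L], 0)

  p2 <- kinetic_parameters(k_a = 1e6, ag_total = 1.2, k_int = 0,
                           k_efflux = 0.3)
  d2 <- ode_rhs(1, c(0, 0.4), p2, constant_input_uM(0))
  expect_equal(d2[1L], 0)
  expect_equal(d2[2L], -0.3 * 0.4)  # pure first-order washout

  expect_error(ode_rhs(1, c(0, 0), p, inp, occupancy_mode = "data_driven"),
               "occupancy")
})

test_that("nonlinear RHS converges to the linear RHS in the large-pool limit", {
  set.seed(7)
  c_eff <- 0.31  # h^-1, held fixed: k_a * ag_total * 1e-6
  ag_big <- 1e9  # uM
  p_nl <- kinetic_parameters(k_a = c_eff / (ag_big * 1e-6), ag_total = ag_big,
                             k_int = 0.2, k_efflux = 0.05)
  p_lin <- kinetic_parameters(k21_lin = c_eff, k_int = 0.2, k_efflux = 0.05,
                              model_variant = "linear")
  for (i in 1:10) {
    st <- runif(2, 0, 2)
    inp <- constant_input_uM(runif(1, 0, 3))
    expect_equal(ode_rhs(0, st, p_nl, inp), ode_rhs(0, st, p_lin, inp),
                 tolerance = 1e-6)
  }
})

test_that("zero input yields identically zero trajectories", {
  p <- params_iodine_like()
  tr <- simulate_trajectory(p, constant_input_uM(0), seq(0, 96, by = 4))
  expect_true(all(tr$q2 == 0))
  expect_true(all(tr$q3 == 0))
  expect_true(all(tr$tumor_total_uM == 0))
})

test_that("adaptive solver reproduces the analytic linear cascade", {
  tg <- seq(0, 96, by = 2)
  pl <- kinetic_parameters(k21_lin = 0.05, k_int = 0.2, k_efflux = 0.03,
                           model_variant = "linear")
  tr <- simulate_trajectory(pl, constant_input_uM(0.5), tg)
  an <- analytic_linear_solution(0.05, 0.2, 0.03, 0.5, tg)
  expect_equal(tr$q2[-1L], an$q2[-1L], tolerance = 1e-6)
  expect_equal(tr$q3[-1L], an$q3[-1L], tolerance = 1e-6)

  # k_efflux = 0 branch: first-stage steady state
  pl0 <- kinetic_parameters(k21_lin = 0.05, k_int = 0.2, k_efflux = 0,
                            model_variant = "linear")
  tr0 <- simulate_trajectory(pl0, constant_input_uM(0.5), c(0, 50, 500))
  expect_equal(tr0$q2[3L], 0.05 * 0.5 / 0.2, tolerance = 1e-5)
})

test_that("analytic linear solution handles special branches", {
  expect_equal(analytic_linear_solution(0.1, 0.2, 0.05, 1, 0),
               list(q2 = 0, q3 = 0))
  # equal-rate branch agrees with nearby general branch
  g <- analytic_linear_solution(0.1, 0.2, 0.2 + 1e-9, 1, c(1, 10, 50))
  e <- analytic_linear_solution(0.1, 0.2, 0.2, 1, c(1, 10, 50))
  expect_equal(g$q3, e$q3, tolerance = 1e-6)
  # general branch vs adaptive ODE on assorted rates
  tg <- c(0, 1, 5, 20, 60, 96)
  for (r in list(c(0.3, 0.04), c(0.05, 0.6), c(1, 1e-3))) {
    pl <- kinetic_parameters(k21_lin = 0.08, k_int = r[1L], k_efflux = r[2L],
                             model_variant = "linear")
    tr <- simulate_trajectory(pl, constant_input_uM(0.7), tg)
    an <- analytic_linear_solution(0.08, r[1L], r[2L], 0.7, tg)
    expect_equal(tr$q2[-1L], an$q2[-1L], tolerance = 1e-6)
    expect_equal(tr$q3[-1L], an$q3[-1L], tolerance = 1e-6)
  }
})

test_that("occupancy approaches but never exceeds the antigen pool", {
  p <- kinetic_parameters(k_a = 1e7, ag_total = 1.2, k_int = 0.2,
                          k_efflux = 0.01)
  tr <- simulate_trajectory(p, constant_input_uM(5), seq(0, 96, by = 0.5))
  expect_lte(max(tr$occupancy), p$ag_total + 1e-9)
  expect_gt(tr$occupancy[length(tr$occupancy)], 0.99 * p$ag_total)
  # saturation bound on random draws from zero initial state
  for (p in draw_params(15, seed = 11)) {
    tr <- simulate_trajectory(p, test_input_uM(injection_record(1000)),
                              seq(0, 96, by = 2))
    expect_lte(max(tr$occupancy), p$ag_total + 1e-9)
    expect_true(all(tr$q2 >= 0) && all(tr$q3 >= 0))
  }
})

test_that("fixed-step Euler and adaptive integration agree", {
  inj <- injection_record(240)
  inp <- test_input_uM(inj)
  tg <- seq(0, 96, by = 8)
  for (p in draw_params(4, seed = 23)) {
    ad <- simulate_trajectory(p, inp, tg)
    eu <- simulate_trajectory(p, inp, tg,
                              solver = solver_config(method = "euler",
                                                     dt = 0.001))
    scale <- max(ad$tumor_total_uM)
    expect_lt(max(abs(ad$tumor_total_uM - eu$tumor_total_uM)) / scale, 0.005)
  }
})

test_that("larger efflux depresses the tumor signal pointwise", {
  inj <- injection_record(180)
  inp <- test_input_uM(inj)
  tg <- seq(0, 96, by = 2)
  lo <- simulate_trajectory(params_zirconium_like(ag_total = 1.2), inp, tg)
  hi_p <- params_zirconium_like(ag_total = 1.2)
  hi_p$k_efflux <- 9 * hi_p$k_efflux
  hi <- simulate_trajectory(hi_p, inp, tg)
  expect_true(all(hi$tumor_total_uM <= lo$tumor_total_uM + 1e-12))
})

test_that("compiled fitting path matches the closure-based solver", {
  inj <- injection_record(180)
  f_uM <- function(t) pidg_to_molar(test_input_pidg()(t), inj)
  tg <- c(0, 4, 24, 48, 72, 96)
  ptab <- immunokin:::.tabulate_input(f_uM, 96)
  for (p in draw_params(5, seed = 31)) {
    tr <- simulate_trajectory(p, input_function(f_uM, unit = "uM"), tg)
    sc <- immunokin:::.simulate_compiled(p, tg, ptab)
    expect_true(sc$ok)
    expect_equal(sc$q2, tr$q2, tolerance = 1e-4)
    expect_equal(sc$q3, tr$q3, tolerance = 1e-4)
  }
})

test_that("trajectory preconditions are enforced", {
  p <- params_iodine_like()
  inp <- constant_input_uM(1)
  expect_error(simulate_trajectory(p, inp, c(1, 2, 3)), "start at 0")
  expect_error(simulate_trajectory(p, inp, c(0, 2, 2)), "increasing")
  expect_error(simulate_trajectory(p, test_input_pidg(), c(0, 1, 2)),
               "injection_record")
})

test_that("parameter container validates and serializes", {
  expect_error(kinetic_parameters(k_a = -1, ag_total = 1, k_int = 0.1,
                                  k_efflux = 0.1), "k_a")
  expect_error(kinetic_parameters(k_int = 0.1, k_efflux = 0.1), "requires")
  expect_error(kinetic_parameters(k_a = 1, ag_total = 1, k_int = 0.1,
                                  k_efflux = 0.1, blood_fraction = 1),
               "blood_fraction")
  expect_error(kinetic_parameters(k_a = 1, ag_total = 1, k_int = 0.1,
                                  k_efflux = 0.1, k21_lin = 0.1),
               "linear variant only")
  p <- params_zirconium_like()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(p, f)
    expect_equal(read_params(f), p)
    unlink(f)
  }
})
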