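test_that("initial conditions are seeded, centred and reproducible", {
  p <- classic_params()
  ss <- select_steady_state(p)
  mesh <- cached_mesh(3)
  opts <- sim_options(subdivisions = 3, seed = 42)
  ic1 <- initial_condition(ss, opts, mesh, p)
  ic2 <- initial_condition(ss, opts, mesh, p)
  expect_identical(ic1, ic2)  # same seed, bitwise identical
  ic3 <- initial_condition(ss, sim_options(subdivisions = 3, seed = 43),
                           mesh, p)
  expect_false(identical(ic1$u, ic3$u))
  # mean within sampling error of u*; uniform(-1,1) has sd 1/sqrt(3)
  se <- opts$sigma * ss$u_star / sqrt(3 * mesh$n_vertices)
  expect_lt(abs(mean(ic1$u) - ss$u_star), 5 * se)
  # sigma -> 0 recovers the uniform steady state
  tiny <- initial_condition(ss, sim_options(subdivisions = 3, sigma = 1e-12),
                            mesh, p)
  expect_equal(tiny$u, rep(ss$u_star, mesh$n_vertices), tolerance = 1e-10)
})

test_that("the uniform steady state is a fixed point of the IMEX step", {
  p <- classic_params()
  ss <- select_steady_state(p)
  mesh <- cached_mesh(3)
  n <- mesh$n_vertices
  # V is set to the exact steady-state value: with it the reactions vanish
  # identically and constants are in the diffusion kernel, so the step is
  # the identity to solver precision. (Using the discrete nonlocal V
  # instead shifts the equilibrium by the constant-quadrature defect.)
  state <- structure(list(u = rep(ss$u_star, n), v = rep(ss$v_star, n),
                          V = ss$V_star), class = "cdc42_fields")
  out <- step_fields(state, 1e-3, p, mesh)
  expect_equal(out$u, state$u, tolerance = 1e-10)
  expect_equal(out$v, state$v, tolerance = 1e-10)
})

test_that("implicit diffusion damps a harmonic like backward Euler", {
  # negligible reactions leave pure diffusion: a degree-3 harmonic decays
  # by 1 / (1 + dt * l(l+1)) per step in u (and with d * l(l+1) in v)
  p <- update_params(classic_params(), gamma = 1e-300)
  mesh <- cached_mesh(3)
  Y <- zonal_harmonic3(mesh)
  state <- structure(list(u = 1 + 0.1 * Y, v = rep(1, mesh$n_vertices),
                          V = 1), class = "cdc42_fields")
  dt <- 1e-3
  out <- step_fields(state, dt, p, mesh)
  proj <- function(x) sum(mesh$areas * Y * x) / sum(mesh$areas * Y^2)
  expect_equal(proj(out$u - 1) / proj(state$u - 1), 1 / (1 + dt * 12),
               tolerance = 2e-3)
})

test_that("each step conserves total protein to near machine precision", {
  p <- classic_params()
  ss <- select_steady_state(p)
  mesh <- cached_mesh(3)
  opts <- sim_options(subdivisions = 3, seed = 7)
  state <- initial_condition(ss, opts, mesh, p)
  mass <- function(s) mesh$volume * s$V + sum(mesh$areas * (s$u + s$v))
  m0 <- mass(state)
  for (i in 1:50) {
    state <- step_fields(state, 5e-3, p, mesh)
    expect_lt(abs(mass(state) - m0) / m0, 1e-10)
  }
})

test_that("simulations are deterministic given identical options", {
  p <- classic_params()
  mesh <- cached_mesh(3)
  o <- sim_options(subdivisions = 3, seed = 5, tau_max = 1)
  t1 <- simulate_to_polarisation(p, o, mesh = mesh)
  t2 <- simulate_to_polarisation(p, o, mesh = mesh)
  expect_identical(t1$u, t2$u)
  expect_identical(t1$summary, t2$summary)
  expect_identical(t1$tau_final, t2$tau_final)
})

test_that("a full polarisation run conserves mass and reports a pole", {
  p <- classic_params()
  mesh <- cached_mesh(4)
  traj <- simulate_to_polarisation(p, sim_options(seed = 11), mesh = mesh)
  expect_equal(traj$termination, "polarised")
  expect_lt(traj$mass_drift, 1e-8)
  pr <- pole_report(traj, mesh)
  expect_equal(pr$pole_count, 1)
  expect_gt(pr$u_max, pr$u_min)
  expect_gt(pr$relative_pole_area, 0)
  # summary taus strictly increasing
  expect_true(all(diff(traj$summary$tau) > 0))
})

test_that("early linear growth matches the dispersion relation", {
  p <- classic_params()
  ss <- select_steady_state(p)
  mesh <- cached_mesh(4)
  dsp <- dispersion(ss, p)
  Y <- zonal_harmonic3(mesh)
  proj <- function(x) sum(mesh$areas * Y * x) / sum(mesh$areas * Y^2)
  state <- structure(
    list(u = ss$u_star + 1e-4 * Y, v = rep(ss$v_star, mesh$n_vertices),
         V = NA_real_), class = "cdc42_fields")
  state$V <- nonlocal_V(state$u, state$v, mesh, p)
  dt <- 5e-5
  op <- step_operator(mesh, p, dt)
  # burn-in lets the perturbation settle onto the dominant eigenvector of
  # the l = 3 mode matrix before the rate is measured
  for (i in 1:2000) state <- step_fields(state, dt, p, mesh, op)
  a0 <- proj(state$u - ss$u_star)
  for (i in 1:2000) state <- step_fields(state, dt, p, mesh, op)
  a1 <- proj(state$u - ss$u_star)
  measured <- log(abs(a1 / a0)) / (2000 * dt)
  expect_equal(measured, dsp$growth_rate[4], tolerance = 0.1 *
                 abs(dsp$growth_rate[4]))
})
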