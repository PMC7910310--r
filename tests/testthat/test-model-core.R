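test_that("parameter constructors validate and derive m = V0/a", {
  p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
  expect_equal(p$m, p$V0 / p$a)
  expect_equal(p$a, 3)
  expect_error(model_params(c1 = -1, c_minus1 = 0.02, c2 = 0.45),
               "strictly positive")
  expect_error(model_params(c1 = Inf, c_minus1 = 0.02, c2 = 0.45), "finite")
  # m stays consistent through updates
  p2 <- update_params(p, V0 = 9, a = 3)
  expect_equal(p2$m, 3)
  expect_error(update_params(p, bogus = 1), "unknown parameter")
})

test_that("reaction kinetics f matches its closed form and nullcline", {
  p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
  expect_equal(reaction_f(0, 0, p), 0)
  expect_equal(reaction_f(1, 1, p), 0.45)  # c2*1 - 1 + 1
  # v = u / (c2 + u^2) is exactly the f = 0 nullcline
  for (u in c(0.1, 0.7, 1.3246, 5)) {
    expect_equal(reaction_f(u, u / (p$c2 + u^2), p), 0, tolerance = 1e-12)
  }
  expect_error(reaction_f(NaN, 1, p), "finite")
})

test_that("membrane flux q obeys its limiting cases", {
  p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
  V <- 1.7
  expect_equal(flux_q(0, 0, V, p), p$c1 * V * p$c_max)
  expect_equal(flux_q(0.8, 0, 0, p), 0)  # no cytosol, no inactive form
  # at any homogeneous steady state f = 0 and -f + q0 = 0 force q = 0
  ss <- find_steady_states(p)
  for (i in seq_len(nrow(ss))) {
    expect_equal(flux_q(ss$u_star[i], ss$v_star[i], ss$V_star[i], p), 0,
                 tolerance = 1e-9)
  }
})

test_that("q0 is q evaluated on the mass-conservation manifold", {
  p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
  expect_equal(
    q0_homogeneous(0, 0, model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)),
    0.05 * 3 * 3 * 2)  # c1 * a * c_max * m
  # depleted cytosol: u + v = m leaves only the dissociation term
  expect_equal(q0_homogeneous(1.5, 0.5, p), -p$c_minus1 * 0.5)
  # identity q0(u, v) = q(u, v, V0 - a (u + v)) on a grid
  g <- expand.grid(u = seq(0, 2, by = 0.25), v = seq(0, 2, by = 0.25))
  expect_equal(q0_homogeneous(g$u, g$v, p),
               flux_q(g$u, g$v, p$V0 - p$a * (g$u + g$v), p),
               tolerance = 1e-13)
})

test_that("nonlocal functional reduces to V0 - a*s for constant fields", {
  p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
  mesh <- cached_mesh(3)
  n <- mesh$n_vertices
  expect_equal(nonlocal_V(rep(0, n), rep(0, n), mesh, p), p$V0)
  # s = m empties the cytosol up to the quadrature defect of the
  # discrete sphere (|Gamma_h| < 4*pi)
  expect_equal(nonlocal_V(rep(p$m / 2, n), rep(p$m / 2, n), mesh, p), 0,
               tolerance = p$V0 * (1 - mesh$surface_area / (4 * pi)) + 1e-10)
  # random field against the direct weighted-sum oracle
  set.seed(1)
  u <- runif(n); v <- runif(n)
  s_bar <- sum(mesh$areas * (u + v)) / mesh$surface_area
  expect_equal(nonlocal_V(u, v, mesh, p),
               p$V0 - (mesh$surface_area / mesh$volume) * s_bar,
               tolerance = 1e-12)
  # depleting beyond V0 is flagged, not fatal
  expect_warning(nonlocal_V(rep(2, n), rep(2, n), mesh, p), "negative")
})

test_that("quadrature error of constant-field integration vanishes under refinement", {
  p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
  err <- vapply(2:4, function(lev) {
    mesh <- cached_mesh(lev)
    n <- mesh$n_vertices
    abs(nonlocal_V(rep(p$m / 2, n), rep(p$m / 2, n), mesh, p))
  }, 0)
  expect_true(all(diff(err) < 0))
  # defect is V0 * (1 - |Gamma_h| / (4*pi)); about 0.12% area error at level 4
  expect_lt(err[3], 0.01)
})

test_that("non-dimensionalisation reproduces the defining ratios and inverts", {
  dp <- dimensional_params(k1 = 0.3, k_minus1 = 0.11, k2 = 0.7,
                           k_minus2 = 0.7, k3 = 0.2, k_max = 4,
                           D_A = 0.01, D_I = 0.01, D_G = 10,
                           R = 2, G0 = 3)
  nd <- nondimensionalise(dp)
  expect_equal(nd$params$c2, 1)        # k2 = k_minus2
  expect_equal(nd$params$d, 1)         # D_I = D_A
  expect_equal(nd$params$gamma, dp$R^2 * dp$k_minus2 / dp$D_A)
  expect_equal(nd$params$c_minus1, dp$k_minus1 / dp$k_minus2)
  expect_equal(nd$params$c1,
               dp$k1 / dp$k_minus2 * sqrt(dp$k_minus2 / dp$k3))
  expect_equal(nd$params$c_max, dp$k_max * sqrt(dp$k3 / dp$k_minus2))
  expect_equal(nd$params$V0, dp$G0 * sqrt(dp$k3 / dp$k_minus2))
  expect_equal(nd$scales$conc_scale, sqrt(dp$k_minus2 / dp$k3))
  expect_equal(nd$scales$time_scale, dp$R^2 / dp$D_A)
  # gamma = 1 when R^2 k_minus2 = D_A
  dp1 <- dimensional_params(k1 = 0.3, k_minus1 = 0.11, k2 = 0.7,
                            k_minus2 = 0.25, k3 = 0.2, k_max = 4,
                            D_A = 1, D_I = 10, D_G = 100, R = 2, G0 = 3)
  expect_equal(nondimensionalise(dp1)$params$gamma, 1)
  # round trip is the identity on the dimensional side
  back <- redimensionalise(nd$params, nd$scales)
  expect_equal(unclass(back), unclass(dp), tolerance = 1e-12)
})

test_that("flat key-value config files round-trip parameters", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "c1 = 0.05", "c_minus1 = 0.03", "c2 = 0.15",
               "gamma = 25", "d = 10"), path)
  p <- read_params_config(path)
  expect_equal(p$c_minus1, 0.03)
  expect_equal(p$c2, 0.15)
  expect_equal(p$c_max, 3)  # default retained
  writeLines("nope = 1", path)
  expect_error(read_params_config(path), "unknown config key")
  writeLines("c1 = banana", path)
  expect_error(read_params_config(path), "non-numeric")
})
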