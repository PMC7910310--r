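# IMEX simulation of the reduced two-state system on the unit sphere.

#' Simulation options
#'
#' Collects the numerical knobs of the surface simulation. Diffusion is
#' treated implicitly (backward Euler, unconditionally stable), reactions
#' explicitly; the step size starts at `dt_init` and grows by `grow_factor`
#' towards `dt_max` whenever the relative field change per step stays below
#' `grow_tol`, and is halved when it exceeds `reject_tol` (which also
#' catches explicit-reaction instability at large reaction strengths).
#'
#' @param subdivisions icosphere refinement level (4 gives 2562 vertices).
#' @param dt_init,dt_max initial and maximal time step (dimensionless time).
#' @param sigma relative amplitude of the uniform initial noise.
#' @param seed RNG seed, recorded in all outputs.
#' @param tau_max time horizon; reached only when no pattern forms.
#' @param stat_window width (in tau) of the stationarity window used by the
#'   pole-recognition termination rule.
#' @param stat_tol maximal relative field change across the stationarity
#'   window for termination.
#' @param contrast_min minimal pattern contrast `(u_max - u_min) / u_mean`
#'   required before termination is considered (guards against declaring a
#'   still-uniform transient stationary).
#' @param reject_tol,grow_tol,grow_factor step-size controls (relative
#'   change per step).
#' @param check_every accepted steps between pole-recognition checks.
#' @param record_every tau interval between summary records.
#' @param theta pole-detection threshold fraction (see [detect_poles()]).
#' @param min_pole_area minimal relative component area counted as a pole.
#' @param store_fields keep intermediate field snapshots (memory-hungry;
#'   summaries are always kept).
#' @return An object of class `cdc42_sim_options`.
#' @export
sim_options <- function(subdivisions = 4, dt_init = 1e-4, dt_max = 1e-2,
                        sigma = 0.05, seed = 1L, tau_max = 50,
                        stat_window = 0.2, stat_tol = 1e-3,
                        contrast_min = 0.5, reject_tol = 0.1,
                        grow_tol = 0.01, grow_factor = 1.2,
                        check_every = 25, record_every = 0.1,
                        theta = 0.5, min_pole_area = 0.01,
                        store_fields = FALSE) {
  stopifnot(sigma > 0, dt_init > 0, dt_max >= dt_init, tau_max > 0,
            reject_tol > grow_tol, grow_factor > 1)
  structure(as.list(environment()), class = "cdc42_sim_options")
}

#' Noisy initial condition around a steady state
#'
#' Perturbs the homogeneous steady state multiplicatively with i.i.d.
#' uniform noise: `u_i = u* (1 + sigma xi_i)`, `v_i = v* (1 + sigma xi_i')`
#' with `xi ~ U(-1, 1)` drawn from the seeded RNG; the cytosolic
#' concentration is then set by the nonlocal functional. The same seed
#' reproduces the same fields exactly.
#'
#' @param ss a steady-state row.
#' @param opts a [sim_options()] object (uses `sigma` and `seed`).
#' @param mesh a [build_icosphere()] mesh.
#' @inheritParams reaction_f
#' @return A list of class `cdc42_fields` with `u`, `v` (vertex fields) and
#'   scalar `V`.
#' @export
initial_condition <- function(ss, opts, mesh, params) {
  set.seed(opts$seed)
  n <- mesh$n_vertices
  u <- ss$u_star * (1 + opts$sigma * stats::runif(n, -1, 1))
  v <- ss$v_star * (1 + opts$sigma * stats::runif(n, -1, 1))
  if (!all(in_trapping_region(u, v, params))) {
    warning("initial condition leaves the trapping region pointwise",
            call. = FALSE)
  }
  structure(list(u = u, v = v, V = nonlocal_V(u, v, mesh, params)),
            class = "cdc42_fields")
}

#' Pre-factorised implicit diffusion operator
#'
#' Builds the sparse Cholesky factorisations of `M + dt * K` and
#' `M + dt * d * K` used by the backward-Euler diffusion solve, so repeated
#' steps at the same `dt` reuse the factors.
#'
#' @inheritParams initial_condition
#' @param dt time step.
#' @return List with factors `fac_u`, `fac_v` and the `dt` they encode.
#' @export
step_operator <- function(mesh, params, dt) {
  stopifnot(dt > 0)
  Au <- Matrix::forceSymmetric(mesh$M + dt * mesh$K)
  Av <- Matrix::forceSymmetric(mesh$M + dt * params$d * mesh$K)
  list(fac_u = Matrix::Cholesky(Au, LDL = FALSE),
       fac_v = Matrix::Cholesky(Av, LDL = FALSE),
       dt = dt)
}

#' One IMEX step of the reduced surface system
#'
#' Advances `(u, v, V)` by one step of size `dt`: the reactions
#' `gamma * f` and `gamma * (-f + q(u, v, V))` are taken explicitly, the
#' diffusion implicitly (backward Euler via the lumped-mass FEM system),
#' and `V` is recomputed from the nonlocal mass-conservation functional
#' after the update, which keeps the total amount
#' `|Omega| V + sum_i w_i (u_i + v_i)` exactly constant.
#'
#' @param state a `cdc42_fields` list.
#' @param dt time step (> 0).
#' @inheritParams initial_condition
#' @param op optional [step_operator()] for this `dt` (built on the fly
#'   when omitted).
#' @return The advanced `cdc42_fields` state.
#' @export
step_fields <- function(state, dt, params, mesh, op = NULL) {
  if (is.null(op)) op <- step_operator(mesh, params, dt)
  stopifnot(abs(op$dt - dt) <= 1e-15 * dt)
  f <- params$c2 * state$v - state$u + state$u^2 * state$v
  q <- params$c1 * state$V * (params$c_max - (state$u + state$v)) -
    params$c_minus1 * state$v
  w <- mesh$areas
  rhs_u <- w * (state$u + dt * params$gamma * f)
  rhs_v <- w * (state$v + dt * params$gamma * (-f + q))
  u1 <- as.vector(Matrix::solve(op$fac_u, rhs_u, system = "A"))
  v1 <- as.vector(Matrix::solve(op$fac_v, rhs_v, system = "A"))
  if (anyNA(u1) || anyNA(v1) || any(!is.finite(u1)) || any(!is.finite(v1))) {
    stop("non-finite state after step (dt = ", dt, ", tau-state dumped in ",
         "condition)", call. = FALSE)
  }
  V1 <- params$V0 - sum(w * (u1 + v1)) / mesh$volume
  structure(list(u = u1, v = v1, V = V1), class = "cdc42_fields")
}

#' Simulate the reduced model on the sphere until polarisation
#'
#' Runs the IMEX scheme from a noisy perturbation of the selected steady
#' state with adaptive step-size control, checking the pole-recognition
#' operator periodically. The run terminates when the pattern is
#' stationary: at least one pole, pole count and relative pole area
#' unchanged across a trailing window of width `stat_window`, sufficient
#' contrast, and maximal relative field change below `stat_tol` across the
#' window. If no such state is reached by `tau_max`, the run ends with
#' termination reason `"no_pattern"`.
#'
#' @inheritParams reaction_f
#' @param opts a [sim_options()] object.
#' @param mesh optional pre-built mesh (rebuilt from
#'   `opts$subdivisions` when omitted).
#' @param ss optional steady state to perturb around; defaults to
#'   [select_steady_state()], falling back to the lowest steady state in
#'   the trapping region.
#' @return An object of class `cdc42_trajectory`: `summary` data.frame
#'   (`tau`, `mass`, `u_max`, `u_min`, `pole_count`, `pole_area`), final
#'   fields `u`, `v`, `V`, `tau_final`, `termination` (`"polarised"`;
#'   `"max_tau"` when a pattern exists but is still drifting at the
#'   horizon, as multi-pole states do while slowly coarsening;
#'   `"no_pattern"` when no pole exists at the horizon), `mass_drift` (max
#'   relative), the seed, parameters and options, and (optionally) stored
#'   snapshots.
#' @export
simulate_to_polarisation <- function(params, opts = sim_options(),
                                     mesh = NULL, ss = NULL) {
  stopifnot(inherits(params, "cdc42_params"),
            inherits(opts, "cdc42_sim_options"))
  if (is.null(mesh)) mesh <- build_icosphere(opts$subdivisions)
  if (is.null(ss)) {
    ss <- select_steady_state(params)
    if (is.null(ss)) {
      all_ss <- find_steady_states(params)
      all_ss <- all_ss[all_ss$in_trapping_region, , drop = FALSE]
      if (!nrow(all_ss)) {
        stop("no steady state in the trapping region to perturb around",
             call. = FALSE)
      }
      ss <- all_ss[1, , drop = FALSE]
    }
  }
  state <- initial_condition(ss, opts, mesh, params)
  w <- mesh$areas
  mass0 <- mesh$volume * state$V + sum(w * (state$u + state$v))

  # dt lives on a fixed geometric ladder dt_init * grow_factor^k, so the
  # adaptive controller revisits a bounded set of step sizes and each
  # Cholesky factorisation is paid exactly once
  k_max <- ceiling(log(opts$dt_max / opts$dt_init) / log(opts$grow_factor))
  ladder <- pmin(opts$dt_init * opts$grow_factor^(0:k_max), opts$dt_max)
  op_cache <- vector("list", k_max + 1)
  get_op <- function(k) {
    if (is.null(op_cache[[k + 1]])) {
      op_cache[[k + 1]] <<- step_operator(mesh, params, ladder[k + 1])
    }
    op_cache[[k + 1]]
  }
  k_dt <- 0L
  dt <- ladder[1]
  op <- get_op(0L)
  tau <- 0
  n_accept <- 0L
  next_record <- 0
  max_drift <- 0
  summary_rows <- list()
  snapshots <- if (opts$store_fields) list() else NULL
  history <- list()  # pole checks for the stationarity window
  termination <- "no_pattern"

  record <- function(poles) {
    mass <- mesh$volume * state$V + sum(w * (state$u + state$v))
    list(tau = tau, mass = mass, u_max = max(state$u), u_min = min(state$u),
         pole_count = poles$count, pole_area = poles$relative_area)
  }

  poles <- detect_poles(state$u, mesh, theta = opts$theta,
                        min_area_frac = opts$min_pole_area)
  summary_rows[[1]] <- record(poles)
  next_record <- opts$record_every

  while (tau < opts$tau_max) {
    new <- tryCatch(step_fields(state, dt, params, mesh, op),
                    error = function(e) NULL)
    rel <- if (is.null(new)) Inf else {
      max(max(abs(new$u - state$u)) / max(abs(state$u), 1e-8),
          max(abs(new$v - state$v)) / max(abs(state$v), 1e-8))
    }
    if (!is.finite(rel) || rel > opts$reject_tol) {
      if (k_dt == 0L) {
        stop("step rejected at the smallest step size (dt_init = ",
             opts$dt_init, ") at tau = ", tau, call. = FALSE)
      }
      k_dt <- max(k_dt - 4L, 0L)  # four rungs down ~ halving
      dt <- ladder[k_dt + 1]
      op <- get_op(k_dt)
      next
    }
    state <- new
    tau <- tau + dt
    n_accept <- n_accept + 1L
    mass <- mesh$volume * state$V + sum(w * (state$u + state$v))
    max_drift <- max(max_drift, abs(mass - mass0) / abs(mass0))

    if (rel < opts$grow_tol && k_dt < k_max) {
      k_dt <- k_dt + 1L
      dt <- ladder[k_dt + 1]
      op <- get_op(k_dt)
    }

    if (n_accept %% opts$check_every == 0L) {
      poles <- detect_poles(state$u, mesh, theta = opts$theta,
                            min_area_frac = opts$min_pole_area)
      history[[length(history) + 1]] <-
        list(tau = tau, count = poles$count, area = poles$relative_area,
             u = state$u)
      # drop entries older than needed for the window comparison
      taus <- vapply(history, `[[`, 0, "tau")
      keep <- taus >= tau - opts$stat_window - 2 * opts$stat_window
      history <- history[keep]
      taus <- taus[keep]
      ref_i <- which(taus <= tau - opts$stat_window)
      if (length(ref_i)) {
        ref <- history[[max(ref_i)]]
        contrast <- (max(state$u) - min(state$u)) /
          max(sum(w * state$u) / sum(w), 1e-12)
        if (poles$count >= 1 && poles$count == ref$count &&
            abs(poles$relative_area - ref$area) <= 0.01 &&
            contrast > opts$contrast_min &&
            max(abs(state$u - ref$u)) / max(abs(state$u)) < opts$stat_tol) {
          termination <- "polarised"
        }
      }
    }

    if (tau >= next_record || termination == "polarised") {
      summary_rows[[length(summary_rows) + 1]] <- record(poles)
      if (opts$store_fields) {
        snapshots[[length(snapshots) + 1]] <-
          list(tau = tau, u = state$u, v = state$v, V = state$V)
      }
      next_record <- next_record + opts$record_every
    }
    if (termination == "polarised") break
  }

  if (termination == "no_pattern" && poles$count >= 1) {
    # a pattern exists but was still drifting at the horizon
    termination <- "max_tau"
  }
  summary <- do.call(rbind, lapply(summary_rows, as.data.frame))
  structure(
    list(summary = summary, u = state$u, v = state$v, V = state$V,
         tau_final = tau, termination = termination,
         mass_drift = max_drift, n_steps = n_accept,
         seed = opts$seed, params = params, opts = opts,
         mesh_level = mesh$subdivisions, snapshots = snapshots),
    class = "cdc42_trajectory")
}

#' @export
print.cdc42_trajectory <- function(x, ...) {
  cat(sprintf(
    "Surface simulation: tau_final = %.3f (%s), %d steps, mass drift %.2e\n",
    x$tau_final, x$termination, x$n_steps, x$mass_drift))
  cat(sprintf("  final u in [%.3f, %.3f], V = %.4f, seed %d\n",
              min(x$u), max(x$u), x$V, x$seed))
  invisible(x)
}
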