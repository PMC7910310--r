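#' Coefficients of the steady-state polynomial
#'
#' At a steady state of the homogeneous system, `f = 0` forces
#' `v = u / (c2 + u^2)`; substituting into `q0 = 0` and clearing the
#' denominator `(c2 + u^2)^2` yields a degree-6 polynomial in `u`:
#' `c1 * a * P(u) * M(u) - c_minus1 * u * (c2 + u^2)`, where
#' `P(u) = c_max * (c2 + u^2) - u * (c2 + 1 + u^2)` and `M(u)` is the same
#' with `m` in place of `c_max`. Its positive real roots are the positive
#' steady states, hence the 0/2/4/6 parity (the polynomial is positive both
#' at `u = 0` and as `u -> Inf`).
#'
#' @inheritParams reaction_f
#' @return Numeric coefficient vector in ascending powers of `u`
#'   (length 7).
#' @keywords internal
steady_state_poly <- function(params) {
  c2 <- params$c2
  # P(u) = -u^3 + b*u^2 - (c2+1)*u + b*c2, ascending coefficients
  cubic <- function(b) c(b * c2, -(c2 + 1), b, -1)
  P <- cubic(params$c_max)
  M <- cubic(params$m)
  PM <- numeric(7)
  for (i in seq_along(P)) {
    PM[i:(i + 3)] <- PM[i:(i + 3)] + P[i] * M
  }
  PM <- params$c1 * params$a * PM
  PM[1:4] <- PM[1:4] - params$c_minus1 * c(0, c2, 0, 1)
  PM
}

steady_state_row <- function(u, params, degenerate = FALSE) {
  v <- u / (params$c2 + u^2)
  V <- params$V0 - params$a * (u + v)
  J <- homogeneous_jacobian(list(u_star = u, v_star = v), params)
  ev <- eigen(J, only.values = TRUE)$values
  data.frame(
    u_star = u, v_star = v, V_star = V,
    in_trapping_region = in_trapping_region(u, v, params),
    satisfies_necessary_condition = necessary_condition(params, u),
    homogeneous_stable = max(Re(ev)) < 0,
    degenerate = degenerate
  )
}

#' Find all positive steady states of the homogeneous system
#'
#' Solves `f(u, v) = q0(u, v) = 0` globally by reducing to the degree-6
#' polynomial of [steady_state_poly()] and extracting all real positive
#' roots (companion-matrix root finding via [polyroot()], then a Newton
#' polish on the polynomial). Each root is returned with
#' `v* = u* / (c2 + u*^2)`, `V* = V0 - a (u* + v*)`, and flags for
#' membership of the trapping region, the necessary condition for
#' diffusion-driven instability, and linear stability of the homogeneous
#' system. Near-multiple roots are flagged `degenerate` (the 0/2/4/6 parity
#' of the positive-root count only holds for simple roots).
#'
#' @inheritParams reaction_f
#' @param tol root classification tolerance: imaginary parts below
#'   `tol * (1 + |root|)` are treated as real, and real roots closer than
#'   `sqrt(tol)` to each other are flagged degenerate.
#' @return A data.frame with one row per positive steady state, sorted by
#'   increasing `u_star`, columns `u_star`, `v_star`, `V_star`,
#'   `in_trapping_region`, `satisfies_necessary_condition`,
#'   `homogeneous_stable`, `degenerate`. Zero rows if no positive steady
#'   state exists.
#' @examples
#' p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
#' find_steady_states(p)
#' @export
find_steady_states <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "cdc42_params"))
  coef <- steady_state_poly(params)
  roots <- polyroot(coef)
  scale <- max(abs(roots), 1)
  real <- abs(Im(roots)) < tol * (1 + scale)
  u <- sort(Re(roots)[real])
  u <- u[u > tol]
  if (!length(u)) {
    out <- steady_state_row(1, params)[0, ]
    return(out)
  }
  # Newton polish on the polynomial itself
  dcoef <- coef[-1] * seq_len(6)
  for (it in 1:3) {
    pval <- vapply(u, function(x) sum(coef * x^(0:6)), 0)
    dval <- vapply(u, function(x) sum(dcoef * x^(0:5)), 0)
    ok <- abs(dval) > .Machine$double.eps * scale
    u[ok] <- u[ok] - pval[ok] / dval[ok]
  }
  degenerate <- rep(FALSE, length(u))
  if (length(u) > 1) {
    close <- diff(u) < sqrt(tol) * (1 + scale)
    degenerate[which(close)] <- TRUE
    degenerate[which(close) + 1] <- TRUE
  }
  out <- do.call(rbind, lapply(seq_along(u), function(i) {
    steady_state_row(u[i], params, degenerate = degenerate[i])
  }))
  rownames(out) <- NULL
  out
}

# Lean selected-root finder used in tight grid loops: smallest positive
# polynomial root inside the necessary-condition bracket, or NA. `params`
# may be a plain list with the cdc42_params fields.
selected_root <- function(params) {
  coef <- steady_state_poly(params)
  roots <- polyroot(coef)
  re <- Re(roots)
  u <- re[abs(Im(roots)) < 1e-9 * (1 + abs(roots))]
  lo <- sqrt(params$c2)
  hi <- min(params$c_max, params$m)
  u <- u[u > lo & u < hi]
  if (!length(u)) return(NA_real_)
  u <- min(u)
  dcoef <- coef[-1] * seq_len(6)
  for (it in 1:3) {
    dv <- sum(dcoef * u^(0:5))
    if (abs(dv) < 1e-300) break
    u <- u - sum(coef * u^(0:6)) / dv
  }
  u
}

#' Select the steady state used for stability analysis and simulation
#'
#' Returns the positive steady state inside the necessary-condition bracket
#' `(sqrt(c2), min(c_max, m))`, taking the smallest `u*` if several lie
#' inside; this mirrors the start-guess rule used to seed the Newton solver.
#'
#' @inheritParams reaction_f
#' @return A one-row steady-state data.frame, or `NULL` if no steady state
#'   lies in the bracket.
#' @export
select_steady_state <- function(params) {
  ss <- find_steady_states(params)
  if (!nrow(ss)) return(NULL)
  ss <- ss[ss$satisfies_necessary_condition, , drop = FALSE]
  if (!nrow(ss)) return(NULL)
  ss[1, , drop = FALSE]
}

#' Newton refinement of a steady state from a start guess
#'
#' Local Newton iteration on the 2-by-2 system `(f, q0) = 0` starting from
#' `u0` with `v0 = u0 / (c2 + u0^2)` (the start-guess rule: any point on the
#' `f = 0` nullcline). If the Jacobian becomes singular or the iteration
#' leaves `(0, 10 * min(c_max, m))`, the solver falls back to bracketed
#' bisection on the reduced polynomial restricted to the nullcline, so a
#' diverging Newton path is never reported as a root.
#'
#' @param u0 start guess for `u*`, ideally inside
#'   `(sqrt(c2), min(c_max, m))`.
#' @inheritParams reaction_f
#' @param tol residual tolerance on `max(|f|, |q0|)`.
#' @param max_iter iteration cap.
#' @return A one-row steady-state data.frame as in [find_steady_states()].
#' @export
newton_refine <- function(u0, params, tol = 1e-12, max_iter = 50) {
  stopifnot(is.finite(u0), u0 > 0)
  c2 <- params$c2
  u <- u0
  v <- u0 / (c2 + u0^2)
  upper <- 10 * min(params$c_max, params$m)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    Fv <- c(reaction_f(u, v, params), q0_homogeneous(u, v, params))
    if (max(abs(Fv)) < tol) { ok <- TRUE; break }
    s <- u + v
    ca <- params$c1 * params$a
    dq0_ds <- -ca * ((params$m - s) + (params$c_max - s))
    J <- matrix(c(2 * u * v - 1, c2 + u^2,
                  dq0_ds, dq0_ds - params$c_minus1),
                2, 2, byrow = TRUE)
    detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    if (!is.finite(detJ) || abs(detJ) < 1e-14) break
    step <- solve(J, Fv)
    u <- u - step[1]
    v <- v - step[2]
    if (!is.finite(u) || !is.finite(v) || u <= 0 || u > upper) break
  }
  if (!ok) {
    # bisection on g(u) = q0(u, u/(c2+u^2)) over a bracket around u0
    g <- function(x) q0_homogeneous(x, x / (c2 + x^2), params)
    grid <- seq(1e-8, upper, length.out = 4096)
    gv <- vapply(grid, g, 0)
    sgn <- which(gv[-1] * gv[-length(gv)] <= 0)
    if (!length(sgn)) {
      stop("Newton iteration diverged and no sign change found for the ",
           "reduced steady-state equation", call. = FALSE)
    }
    # take the bracket whose midpoint is closest to the start guess
    mid <- (grid[sgn] + grid[sgn + 1]) / 2
    i <- sgn[which.min(abs(mid - u0))]
    r <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-14)
    u <- r$root
    v <- u / (c2 + u^2)
  }
  steady_state_row(u, params)
}

#' Trapping-region membership
#'
#' The physically admissible region of the homogeneous dynamics is
#' `{u >= 0, v >= 0, u + v <= min(c_max, m)}`: membrane concentrations are
#' non-negative, the membrane cannot hold more than `c_max`, and the
#' cytosol cannot be depleted below zero (`u + v <= m` keeps
#' `V = V0 - a(u+v) >= 0`). Homogeneous trajectories started inside can
#' never leave.
#'
#' @param u,v concentrations (vectorised).
#' @inheritParams reaction_f
#' @param tol slack allowed on each inequality (useful when checking
#'   numerically integrated trajectories).
#' @return Logical vector.
#' @export
in_trapping_region <- function(u, v, params, tol = 0) {
  bound <- min(params$c_max, params$m)
  u >= -tol & v >= -tol & (u + v) <= bound + tol
}

#' Necessary condition for diffusion-driven instability
#'
#' A steady state can only lose stability to spatial perturbations if
#' `sqrt(c2) < min(c_max, m)` and `u*` lies in the open interval
#' `(sqrt(c2), min(c_max, m))`.
#'
#' @inheritParams reaction_f
#' @param ss a steady-state row from [find_steady_states()], or a numeric
#'   `u*` value.
#' @return Logical.
#' @export
necessary_condition <- function(params, ss) {
  u <- if (is.numeric(ss)) ss else ss$u_star
  bound <- min(params$c_max, params$m)
  root_c2 <- sqrt(params$c2)
  root_c2 < bound & u > root_c2 & u < bound
}

#' Integrate the homogeneous (well-mixed) system
#'
#' Solves `du/dtau = gamma * f(u, v)`,
#' `dv/dtau = gamma * (-f(u, v) + q0(u, v))` with a stiff-capable solver
#' (`deSolve::ode`, lsoda). The sign of the second equation follows the
#' full surface system, which is the only choice consistent with mass
#' conservation: `V = V0 - a (u + v)` then evolves as
#' `dV/dtau = -a * gamma * q0`.
#'
#' @param u0,v0 initial averages.
#' @inheritParams reaction_f
#' @param horizon final dimensionless time.
#' @param n_out number of output times (dense, equally spaced from 0).
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `tau`, `u_bar`, `v_bar`, `V_bar`.
#' @export
integrate_homogeneous <- function(u0, v0, params, horizon, n_out = 201,
                                  rtol = 1e-9, atol = 1e-12) {
  check_finite_args(u0 = u0, v0 = v0, horizon = horizon)
  rhs <- function(t, y, p) {
    f <- reaction_f(y[1], y[2], params)
    q0 <- q0_homogeneous(y[1], y[2], params)
    list(params$gamma * c(f, -f + q0))
  }
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(c(u = u0, v = v0), times, rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("homogeneous integration failed (step-size collapse); last valid ",
         "time ", max(sol[, 1]), call. = FALSE)
  }
  data.frame(tau = sol[, 1], u_bar = sol[, 2], v_bar = sol[, 3],
             V_bar = params$V0 - params$a * (sol[, 2] + sol[, 3]))
}

#' Write a steady-state table to CSV
#'
#' @param ss a steady-state data.frame from [find_steady_states()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_steady_states <- function(ss, path) {
  utils::write.csv(ss, path, row.names = FALSE)
  invisible(path)
}
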