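#' Membrane activation kinetics f(u, v)
#'
#' Net rate of production of the active form on the membrane:
#' `f(u, v) = c2 * v - u + u^2 * v`, combining GEF/GAP-driven activation
#' (`c2 * v`), first-order inactivation (`-u`) and the quadratic positive
#' feedback loop (`u^2 * v`).
#'
#' @param u active-form concentration (scalar or vector field).
#' @param v inactive membrane-form concentration, same shape as `u`.
#' @param params a [model_params()] object.
#' @return Elementwise reaction rate.
#' @export
reaction_f <- function(u, v, params) {
  check_finite_args(u = u, v = v)
  params$c2 * v - u + u^2 * v
}

#' Membrane flux q(u, v, V)
#'
#' Net influx of inactive Cdc42 onto the membrane from the cytosol:
#' `q(u, v, V) = c1 * V * (c_max - (u + v)) - c_minus1 * v`. Delivery is
#' proportional to the cytosolic concentration `V` and to the free membrane
#' capacity `c_max - (u + v)`; dissociation removes the inactive form at
#' rate `c_minus1`.
#'
#' @param u,v membrane concentrations (equal shapes).
#' @param V cytosolic GDI-bound concentration (scalar under the fast-cytosol
#'   reduction).
#' @inheritParams reaction_f
#' @return Elementwise flux rate.
#' @export
flux_q <- function(u, v, V, params) {
  check_finite_args(u = u, v = v, V = V)
  params$c1 * V * (params$c_max - (u + v)) - params$c_minus1 * v
}

#' Homogeneous flux q0(u, v)
#'
#' The flux term of the spatially averaged system. Replacing the cytosolic
#' concentration by its mass-conservation value `V = V0 - a * (u + v)` (with
#' `m = V0 / a`) gives
#' `q0(u, v) = c1 * a * (c_max - s) * (m - s) - c_minus1 * v`, `s = u + v`.
#'
#' @param u_bar,v_bar spatial averages of the membrane concentrations.
#' @inheritParams reaction_f
#' @return Elementwise rate.
#' @export
q0_homogeneous <- function(u_bar, v_bar, params) {
  check_finite_args(u_bar = u_bar, v_bar = v_bar)
  s <- u_bar + v_bar
  params$c1 * params$a * (params$c_max - s) * (params$m - s) -
    params$c_minus1 * v_bar
}

#' Cytosolic concentration from the nonlocal mass-conservation functional
#'
#' Under the fast-cytosol reduction the cytosolic pool is spatially uniform
#' and slaved to the membrane load:
#' `V = V0 - (1 / |Omega|) * integral_Gamma (u + v) ds`, with
#' `|Omega| = 4 * pi / 3` for the unit ball. The surface integral uses the
#' mesh's lumped vertex areas. A negative value signals a state outside the
#' physical region and is reported with a warning, not an error, since small
#' transient undershoots can arise from quadrature on the discrete sphere.
#'
#' @param u,v vertex fields on `mesh`.
#' @param mesh a [build_icosphere()] mesh.
#' @inheritParams reaction_f
#' @return The scalar cytosolic concentration.
#' @export
nonlocal_V <- function(u, v, mesh, params) {
  stopifnot(length(u) == mesh$n_vertices, length(v) == mesh$n_vertices)
  V <- params$V0 - sum(mesh$areas * (u + v)) / mesh$volume
  if (V < 0) {
    warning("nonlocal cytosolic concentration is negative (state outside ",
            "the physical region)", call. = FALSE)
  }
  V
}

check_finite_args <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (!is.numeric(args[[nm]]) || anyNA(args[[nm]]) ||
        any(!is.finite(args[[nm]]))) {
      stop("'", nm, "' must be finite numeric", call. = FALSE)
    }
  }
  invisible(NULL)
}
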