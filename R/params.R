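#' Dimensionless model parameters
#'
#' Constructs the parameter set of the dimensionless bulk-surface Cdc42
#' model. Membrane kinetics are governed by the relative influx `c1`
#' (GDI-mediated delivery of inactive Cdc42 from the cytosol), the relative
#' dissociation `c_minus1` (extraction back into the cytosol), the relative
#' activation `c2` (net GEF/GAP activation-inactivation module), the maximum
#' membrane load `c_max`, the total average concentration `V0`, the reaction
#' strength `gamma` (ratio of reaction to diffusion rates, proportional to
#' membrane area) and the relative diffusivity `d` of the inactive membrane
#' form. The geometry enters through `a`, the surface-to-volume ratio, which
#' is exactly 3 for the unit ball; `m = V0 / a` is the cytosolic capacity of
#' the membrane (derived, never set directly).
#'
#' @param c1 relative influx rate (> 0).
#' @param c_minus1 relative dissociation rate (> 0).
#' @param c2 relative activation rate (> 0).
#' @param c_max maximum membrane-bound concentration (> 0).
#' @param V0 total average concentration of all forms (> 0).
#' @param gamma relative reaction strength (> 0).
#' @param d relative diffusion of the inactive membrane form (> 0; >= 1 is
#'   expected for simulations since the inactive form diffuses faster).
#' @param a surface area / volume ratio of the domain; 3 for the unit ball.
#' @return An object of class `cdc42_params` (a named list including the
#'   derived `m = V0 / a`).
#' @examples
#' p <- model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45)
#' p$m  # V0 / a = 2
#' @export
model_params <- function(c1, c_minus1, c2, c_max = 3, V0 = 6, gamma = 25,
                         d = 10, a = 3) {
  vals <- c(c1 = c1, c_minus1 = c_minus1, c2 = c2, c_max = c_max, V0 = V0,
            gamma = gamma, d = d, a = a)
  if (!all(is.finite(vals))) {
    stop("all model parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals <= 0)) {
    bad <- names(vals)[vals <= 0]
    stop("model parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(c1 = c1, c_minus1 = c_minus1, c2 = c2, c_max = c_max, V0 = V0,
         gamma = gamma, d = d, a = a, m = V0 / a),
    class = "cdc42_params"
  )
}

#' @export
print.cdc42_params <- function(x, ...) {
  cat("Dimensionless Cdc42 bulk-surface model parameters\n")
  cat(sprintf("  kinetics:  c1 = %g, c_minus1 = %g, c2 = %g, c_max = %g\n",
              x$c1, x$c_minus1, x$c2, x$c_max))
  cat(sprintf("  transport: gamma = %g, d = %g\n", x$gamma, x$d))
  cat(sprintf("  mass/geometry: V0 = %g, a = %g, m = V0/a = %g\n",
              x$V0, x$a, x$m))
  invisible(x)
}

#' Update model parameters
#'
#' Returns a copy of `params` with the named fields replaced; the derived
#' field `m = V0 / a` is recomputed so it can never go stale.
#'
#' @param params a `cdc42_params` object.
#' @param ... named scalar replacements among c1, c_minus1, c2, c_max, V0,
#'   gamma, d, a.
#' @return A new `cdc42_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cdc42_params"))
  repl <- list(...)
  allowed <- c("c1", "c_minus1", "c2", "c_max", "V0", "gamma", "d", "a")
  bad <- setdiff(names(repl), allowed)
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- params[allowed]
  args[names(repl)] <- repl
  do.call(model_params, args)
}

#' Dimensional rate constants for the Cdc42 model
#'
#' Bundles the dimensional parameters of the bulk-surface model before
#' non-dimensionalisation: mass-action rate constants for membrane influx
#' (`k1`), dissociation (`k_minus1`), activation (`k2`), inactivation
#' (`k_minus2`) and the quadratic positive feedback (`k3`), the maximum
#' membrane concentration `k_max`, the diffusivities of the active membrane
#' form (`D_A`), inactive membrane form (`D_I`) and cytosolic GDI-bound form
#' (`D_G`), the cell radius `R` and the initial cytosolic concentration `G0`.
#'
#' @param k1,k_minus1,k2,k_minus2,k3,k_max rate constants, all > 0.
#' @param D_A,D_I,D_G diffusivities, all > 0.
#' @param R cell radius (> 0).
#' @param G0 initial cytosolic GDI-bound concentration (> 0).
#' @return An object of class `cdc42_dimensional`.
#' @export
dimensional_params <- function(k1, k_minus1, k2, k_minus2, k3, k_max,
                               D_A, D_I, D_G, R, G0) {
  vals <- c(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_minus2 = k_minus2,
            k3 = k3, k_max = k_max, D_A = D_A, D_I = D_I, D_G = D_G,
            R = R, G0 = G0)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all dimensional parameters must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "cdc42_dimensional")
}

#' Non-dimensionalise the Cdc42 model
#'
#' Maps dimensional rate constants onto the dimensionless parameter set.
#' Concentrations are scaled by `sqrt(k_minus2 / k3)` (the concentration
#' scale set by inactivation vs feedback), time by `R^2 / D_A` (membrane
#' diffusion time), so that
#' `gamma = R^2 k_minus2 / D_A`, `c1 = (k1 / k_minus2) sqrt(k_minus2 / k3)`,
#' `c_minus1 = k_minus1 / k_minus2`, `c2 = k2 / k_minus2`,
#' `c_max = k_max sqrt(k3 / k_minus2)`, `d = D_I / D_A`, `D = D_G / D_A`
#' and `V0 = G0 sqrt(k3 / k_minus2)`.
#'
#' @param dp a `cdc42_dimensional` object.
#' @param a surface-to-volume ratio of the dimensionless domain (3 for the
#'   unit ball).
#' @return A list with elements `params` (`cdc42_params`) and `scales`
#'   (concentration scale, time scale, `R`, `D_A` and the cytosolic
#'   diffusion ratio `D = D_G / D_A`, which the reduced model takes to
#'   infinity).
#' @seealso [redimensionalise()] for the inverse map.
#' @export
nondimensionalise <- function(dp, a = 3) {
  stopifnot(inherits(dp, "cdc42_dimensional"))
  conc_scale <- sqrt(dp$k_minus2 / dp$k3)
  time_scale <- dp$R^2 / dp$D_A
  params <- model_params(
    c1 = dp$k1 / dp$k_minus2 * conc_scale,
    c_minus1 = dp$k_minus1 / dp$k_minus2,
    c2 = dp$k2 / dp$k_minus2,
    c_max = dp$k_max / conc_scale,
    V0 = dp$G0 / conc_scale,
    gamma = dp$R^2 * dp$k_minus2 / dp$D_A,
    d = dp$D_I / dp$D_A,
    a = a
  )
  list(params = params,
       scales = list(conc_scale = conc_scale, time_scale = time_scale,
                     R = dp$R, D_A = dp$D_A, D = dp$D_G / dp$D_A))
}

#' Recover dimensional parameters from a dimensionless set
#'
#' Inverse of [nondimensionalise()] given the retained scales.
#'
#' @param params a `cdc42_params` object.
#' @param scales the `scales` element returned by [nondimensionalise()].
#' @return A `cdc42_dimensional` object.
#' @export
redimensionalise <- function(params, scales) {
  stopifnot(inherits(params, "cdc42_params"))
  k_minus2 <- params$gamma / scales$time_scale
  k3 <- k_minus2 / scales$conc_scale^2
  dimensional_params(
    k1 = params$c1 * k_minus2 / scales$conc_scale,
    k_minus1 = params$c_minus1 * k_minus2,
    k2 = params$c2 * k_minus2,
    k_minus2 = k_minus2,
    k3 = k3,
    k_max = params$c_max * scales$conc_scale,
    D_A = scales$D_A,
    D_I = params$d * scales$D_A,
    D_G = scales$D * scales$D_A,
    R = scales$R,
    G0 = params$V0 * scales$conc_scale
  )
}
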