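# Linear stability analysis: dispersion over the sphere spectrum and
# classification into classic / non-classic diffusion-driven instability.

# Largest real part among the eigenvalues of [[A, B], [C, E]] (vectorised).
max_re_eig2 <- function(A, B, C, E) {
  tr2 <- (A + E) / 2
  disc <- (A - E)^2 / 4 + B * C
  out <- tr2
  pos <- disc >= 0
  out[pos] <- tr2[pos] + sqrt(disc[pos])
  out
}

# Partial derivatives of f and of q (at fixed V = V*) and of q0 at a steady
# state; the local reaction Jacobian drives the spatial modes, the
# mass-coupled Jacobian drives the homogeneous (l = 0) mode.
linearisation_terms <- function(ss, params) {
  u <- ss$u_star
  v <- ss$v_star
  s <- u + v
  Vs <- params$V0 - params$a * s
  f_u <- 2 * u * v - 1
  f_v <- params$c2 + u^2
  q_u <- -params$c1 * Vs
  q_v <- -params$c1 * Vs - params$c_minus1
  dq0_ds <- -params$c1 * params$a *
    ((params$m - s) + (params$c_max - s))
  list(f_u = f_u, f_v = f_v, q_u = q_u, q_v = q_v,
       q0_u = dq0_ds, q0_v = dq0_ds - params$c_minus1, V_star = Vs)
}

#' Jacobian of the homogeneous system at a steady state
#'
#' The Jacobian of `(gamma * f, gamma * (-f + q0))` at `(u*, v*)`. Unlike
#' the local reaction Jacobian used for spatial modes, the `q0` derivatives
#' carry the mass-conservation coupling (the cytosolic pool responds to a
#' uniform change in membrane load); the difference between the two is what
#' makes non-classic instability possible.
#'
#' @param ss a steady-state row (needs `u_star`, `v_star`).
#' @inheritParams reaction_f
#' @return A 2x2 numeric matrix.
#' @export
homogeneous_jacobian <- function(ss, params) {
  lt <- linearisation_terms(ss, params)
  params$gamma * matrix(
    c(lt$f_u, lt$f_v,
      -lt$f_u + lt$q0_u, -lt$f_v + lt$q0_v),
    2, 2, byrow = TRUE)
}

#' Mode matrix at squared wavenumber k^2
#'
#' Linearisation of the reduced surface system around `(u*, v*)` for a
#' spatial mode with Laplace-Beltrami eigenvalue `k2`. For non-constant
#' modes (spherical-harmonic degree l >= 1) the perturbation integrates to
#' zero over the sphere, so the nonlocal cytosolic term drops out and `q`
#' is linearised at fixed `V = V*`:
#' `gamma * J_loc - diag(k2, d * k2)` with
#' `J_loc = [[f_u, f_v], [-f_u + q_u, -f_v + q_v]]`,
#' `q_u = -c1 V*`, `q_v = -c1 V* - c_minus1`.
#'
#' @inheritParams homogeneous_jacobian
#' @param k2 squared wavenumber (>= 0); on the unit sphere `k2 = l (l + 1)`.
#' @return A 2x2 numeric matrix.
#' @export
mode_matrix <- function(ss, params, k2) {
  stopifnot(is.finite(k2), k2 >= 0)
  lt <- linearisation_terms(ss, params)
  params$gamma * matrix(
    c(lt$f_u, lt$f_v,
      -lt$f_u + lt$q_u, -lt$f_v + lt$q_v),
    2, 2, byrow = TRUE) - diag(c(k2, params$d * k2))
}

#' Dispersion relation over the spherical-harmonic spectrum
#'
#' Computes the largest real eigenvalue part of the linearised system for
#' each admissible wavenumber on the unit sphere, `k2 = l (l + 1)` for
#' degree `l = 1, ..., l_max`, plus the homogeneous mode `l = 0` which uses
#' the mass-coupled Jacobian. The result carries the instability
#' classification (see [classify()]).
#'
#' @inheritParams homogeneous_jacobian
#' @param l_max largest spherical-harmonic degree scanned (default 50; the
#'   unstable band sits far below this for reaction strengths up to a few
#'   hundred).
#' @return An object of class `cdc42_dispersion`: list with `degree`
#'   (0:l_max), `growth_rate` (max Re eigenvalue per degree),
#'   `unstable_degrees` (degrees l >= 1 with positive growth),
#'   `classification` and `reason`.
#' @export
dispersion <- function(ss, params, l_max = 50) {
  stopifnot(l_max >= 1)
  lt <- linearisation_terms(ss, params)
  g <- params$gamma
  A <- g * lt$f_u
  B <- g * lt$f_v
  C <- g * (-lt$f_u + lt$q_u)
  E <- g * (-lt$f_v + lt$q_v)
  l <- seq_len(l_max)
  k2 <- l * (l + 1)
  growth_l <- max_re_eig2(A - k2, B, C, E - params$d * k2)
  J0 <- homogeneous_jacobian(ss, params)
  growth0 <- max(Re(eigen(J0, only.values = TRUE)$values))
  growth <- c(growth0, growth_l)
  unstable <- l[growth_l > 0]
  if (growth0 >= 0) {
    cls <- list(label = "none", reason = "homogeneous_unstable")
  } else if (!length(unstable)) {
    cls <- list(label = "none", reason = "no_unstable_mode")
  } else {
    cls <- classify_local(lt$f_u, lt$f_v, lt$q_u, lt$q_v, params$d)
  }
  structure(
    list(degree = 0:l_max, growth_rate = growth, unstable_degrees = unstable,
         classification = cls$label, reason = cls$reason,
         det_local = lt$f_u * (-lt$f_v + lt$q_v) -
           lt$f_v * (-lt$f_u + lt$q_u),
         steady_state = ss),
    class = "cdc42_dispersion")
}

#' @export
print.cdc42_dispersion <- function(x, ...) {
  cat("Dispersion relation on the unit sphere (k^2 = l(l+1))\n")
  cat(sprintf("  classification: %s (%s)\n", x$classification, x$reason))
  if (length(x$unstable_degrees)) {
    cat("  unstable degrees:", paste(x$unstable_degrees, collapse = " "),
        "\n")
  } else {
    cat("  no unstable degrees\n")
  }
  invisible(x)
}

# Algebraic (continuous-wavenumber) Turing conditions on the local reaction
# Jacobian J_loc = [[f_u, f_v], [-f_u + q_u, -f_v + q_v]]. The reaction
# strength gamma only rescales the wavenumber axis, so these conditions are
# gamma-free:
# * non-classic: det(J_loc) < 0 (the perturbed state is a saddle for small
#   wavenumbers, whatever d) or tr(J_loc) >= 0 with det > 0 (unstable
#   node/spiral at small wavenumbers) -- both independent of d;
# * classic: J_loc a stable node/spiral (tr < 0, det > 0) destabilised by
#   unequal diffusion, i.e. d f_u' + g_v' > 0 and
#   (d f_u' + g_v')^2 >= 4 d det(J_loc); impossible at d = 1 where the
#   first condition reduces to tr(J_loc) > 0.
# |det| below det_tol is reported indeterminate (saddle/node boundary).
classify_local <- function(f_u, f_v, q_u, q_v, d, det_tol = 1e-10) {
  A <- f_u
  B <- f_v
  C <- -f_u + q_u
  E <- -f_v + q_v
  det_loc <- A * E - B * C
  if (abs(det_loc) < det_tol) {
    return(list(label = "indeterminate", reason = "saddle_node_boundary"))
  }
  if (det_loc < 0) {
    return(list(label = "nonclassic", reason = "local_reaction_saddle"))
  }
  if (A + E >= 0) {
    return(list(label = "nonclassic",
                reason = "local_reaction_unstable_node"))
  }
  h <- d * A + E
  if (h > 0 && h^2 >= 4 * d * det_loc) {
    list(label = "classic", reason = "diffusion_driven_node_instability")
  } else {
    list(label = "none", reason = "no_unstable_wavenumber")
  }
}

#' Classify a parameter set: classic, non-classic, or no symmetry breaking
#'
#' Selects the steady state inside the necessary-condition bracket (see
#' [select_steady_state()]) and applies the algebraic
#' (continuous-wavenumber) Turing conditions to its linearisation:
#' * `"none"` if there is no admissible steady state, the homogeneous
#'   (mass-coupled) Jacobian is unstable, or no wavenumber can grow;
#' * `"nonclassic"` if the local reaction Jacobian at fixed `V*` is a
#'   saddle (`det < 0`): the instability is driven by the bulk-surface
#'   mass coupling, is independent of the relative diffusion `d`, and is
#'   open even at `d = 1`;
#' * `"classic"` if the local reaction Jacobian is a stable node/spiral
#'   destabilised by unequal surface diffusion
#'   (`d f_u + g_v > 0` and `(d f_u + g_v)^2 >= 4 d det`), the textbook
#'   Turing route, impossible at `d = 1`;
#' * `"indeterminate"` on the saddle/node boundary (|det| below
#'   tolerance); such points are excluded from region-map area statistics.
#'
#' These conditions are independent of the reaction strength `gamma`,
#' which only rescales the wavenumber axis: they say whether the reaction
#' system can break symmetry at all. Whether an admissible spherical
#' harmonic on the unit sphere actually falls inside the unstable band for
#' the given `gamma` is reported separately by [dispersion()]
#' (`unstable_degrees`), which is what decides if a simulated pattern can
#' form.
#'
#' @inheritParams reaction_f
#' @param ss optional steady-state row; computed via [select_steady_state()]
#'   when `NULL`.
#' @return A character scalar with attribute `reason`.
#' @examples
#' classify(model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45, d = 10))
#' @export
classify <- function(params, ss = NULL) {
  if (is.null(ss)) ss <- select_steady_state(params)
  if (is.null(ss)) {
    return(structure("none", reason = "no_admissible_steady_state"))
  }
  J0 <- homogeneous_jacobian(ss, params)
  if (max(Re(eigen(J0, only.values = TRUE)$values)) >= 0) {
    return(structure("none", reason = "homogeneous_unstable"))
  }
  lt <- linearisation_terms(ss, params)
  cls <- classify_local(lt$f_u, lt$f_v, lt$q_u, lt$q_v, params$d)
  structure(cls$label, reason = cls$reason)
}

#' Map a two-parameter plane into instability regions
#'
#' Classifies every point of a grid over two kinetic parameters (two of
#' `c1`, `c_minus1`, `c2`), for each relative diffusion in `d_list`. The
#' steady state and the local reaction Jacobian do not depend on `d`, so
#' they are computed once per grid point; only the spatial-mode scan is
#' repeated per `d`. Classic regions are nested across `d` (the classic set
#' at smaller `d` is contained in that at larger `d`) while the non-classic
#' label is `d`-independent.
#'
#' @param axes character vector of length 2 naming the swept parameters.
#' @param ranges list of two numeric ranges `c(min, max)`; grids are open at
#'   0 by construction when `min > 0`.
#' @param params a [model_params()] object supplying the fixed parameters.
#' @param d_list relative diffusions to classify at.
#' @param n grid resolution per axis (scalar or length 2).
#' @return An object of class `cdc42_region_map`: list with `axes`,
#'   `grid1`, `grid2`, `d_list`, `label` (array n1 x n2 x length(d_list) of
#'   labels), `nonclassic` and `none` logical matrices (d-independent
#'   companions), and `n_indeterminate`.
#' @export
map_parameter_plane <- function(axes, ranges, params, d_list = c(5, 10, 30),
                                n = 200) {
  stopifnot(length(axes) == 2,
            all(axes %in% c("c1", "c_minus1", "c2")),
            axes[1] != axes[2], length(d_list) >= 1)
  n <- rep(n, length.out = 2)
  stopifnot(all(n >= 2))
  grid1 <- seq(ranges[[1]][1], ranges[[1]][2], length.out = n[1])
  grid2 <- seq(ranges[[2]][1], ranges[[2]][2], length.out = n[2])
  pts <- expand.grid(x1 = grid1, x2 = grid2, KEEP.OUT.ATTRS = FALSE)
  npt <- nrow(pts)

  # d-independent pass: selected steady state and linearisation per point.
  # The inner loop avoids the data.frame-building public path: only the
  # selected root and the Jacobian entries are needed per point.
  f_u <- f_v <- q_u <- q_v <- growth0 <- rep(NA_real_, npt)
  has_ss <- rep(FALSE, npt)
  pi <- unclass(params)
  for (i in seq_len(npt)) {
    pi[[axes[1]]] <- pts$x1[i]
    pi[[axes[2]]] <- pts$x2[i]
    u <- selected_root(pi)
    if (is.na(u)) next
    v <- u / (pi$c2 + u^2)
    s <- u + v
    Vs <- pi$V0 - pi$a * s
    f_u[i] <- 2 * u * v - 1
    f_v[i] <- pi$c2 + u^2
    q_u[i] <- -pi$c1 * Vs
    q_v[i] <- -pi$c1 * Vs - pi$c_minus1
    dq0 <- -pi$c1 * pi$a * ((pi$m - s) + (pi$c_max - s))
    growth0[i] <- max_re_eig2(f_u[i], f_v[i],
                              -f_u[i] + dq0,
                              -f_v[i] + dq0 - pi$c_minus1)
    has_ss[i] <- TRUE
  }
  A <- f_u; B <- f_v
  C <- -f_u + q_u; E <- -f_v + q_v
  det_loc <- A * E - B * C
  tr_loc <- A + E

  labels <- array(NA_character_, dim = c(n[1], n[2], length(d_list)))
  ok <- has_ss & growth0 < 0
  for (j in seq_along(d_list)) {
    d <- d_list[j]
    h <- d * A + E
    lab <- rep("none", npt)
    lab[ok & abs(det_loc) <= 1e-10] <- "indeterminate"
    lab[ok & (det_loc < -1e-10 |
                (det_loc > 1e-10 & tr_loc >= 0))] <- "nonclassic"
    lab[ok & det_loc > 1e-10 & tr_loc < 0 &
          h > 0 & h^2 >= 4 * d * det_loc] <- "classic"
    labels[, , j] <- lab
  }
  nonclassic <- matrix(labels[, , 1] == "nonclassic", n[1], n[2])
  structure(
    list(axes = axes, grid1 = grid1, grid2 = grid2, d_list = d_list,
         label = labels, nonclassic = nonclassic,
         none = matrix(labels[, , 1] == "none", n[1], n[2]),
         det_local = matrix(det_loc, n[1], n[2]),
         n_indeterminate = sum(labels == "indeterminate"),
         params = params),
    class = "cdc42_region_map")
}

#' @export
print.cdc42_region_map <- function(x, ...) {
  cat(sprintf("Instability region map over (%s, %s), %d x %d grid\n",
              x$axes[1], x$axes[2], length(x$grid1), length(x$grid2)))
  for (j in seq_along(x$d_list)) {
    tab <- table(factor(x$label[, , j],
                        levels = c("classic", "nonclassic", "none",
                                   "indeterminate")))
    cat(sprintf("  d = %g: classic %d, nonclassic %d, none %d", x$d_list[j],
                tab[["classic"]], tab[["nonclassic"]], tab[["none"]]))
    if (tab[["indeterminate"]] > 0) {
      cat(sprintf(", indeterminate %d (excluded)", tab[["indeterminate"]]))
    }
    cat("\n")
  }
  invisible(x)
}

#' Long-format view of a region map
#'
#' @param x a `cdc42_region_map`.
#' @param ... unused.
#' @return A data.frame with columns named after the two axes plus `d` and
#'   `label`.
#' @export
as.data.frame.cdc42_region_map <- function(x, ...) {
  out <- do.call(rbind, lapply(seq_along(x$d_list), function(j) {
    df <- expand.grid(x1 = x$grid1, x2 = x$grid2, KEEP.OUT.ATTRS = FALSE)
    df$d <- x$d_list[j]
    df$label <- as.vector(x$label[, , j])
    df
  }))
  names(out)[1:2] <- x$axes
  rownames(out) <- NULL
  out
}

#' Write a region map as long-format CSV
#'
#' @param map a `cdc42_region_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Plot a region map with layered classic regions
#'
#' Renders the five-level colouring: classic regions for each `d` drawn in
#' layers with the smallest `d` on top (classic sets are nested, so smaller
#' `d` regions sit inside larger ones), then the d-independent non-classic
#' region, then no-symmetry-breaking. Uses ggplot2 when available,
#' otherwise base `image()`.
#'
#' @param map a `cdc42_region_map`.
#' @param file optional PNG path; when given the plot is written there.
#' @return The ggplot object (or `NULL` for the base fallback), invisibly.
#' @export
plot_region_map <- function(map, file = NULL) {
  d_sorted <- sort(map$d_list, decreasing = TRUE)
  lev <- c(paste0("classic d=", sort(map$d_list)), "nonclassic", "none")
  df <- expand.grid(x1 = map$grid1, x2 = map$grid2, KEEP.OUT.ATTRS = FALSE)
  layer <- rep("none", nrow(df))
  for (d in d_sorted) {  # largest first; smaller d overwrites (on top)
    j <- match(d, map$d_list)
    lab <- as.vector(map$label[, , j])
    layer[lab == "classic"] <- paste0("classic d=", d)
  }
  layer[as.vector(map$nonclassic)] <- "nonclassic"
  df$region <- factor(layer, levels = lev)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$x1, y = .data$x2, fill = .data$region)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_d(drop = FALSE) +
      ggplot2::labs(x = map$axes[1], y = map$axes[2], fill = NULL) +
      ggplot2::theme_minimal()
    if (!is.null(file)) {
      ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
    }
    return(invisible(p))
  }
  z <- matrix(as.integer(df$region), length(map$grid1), length(map$grid2))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 750)
    on.exit(grDevices::dev.off())
  }
  graphics::image(map$grid1, map$grid2, z, xlab = map$axes[1],
                  ylab = map$axes[2], col = grDevices::hcl.colors(length(lev)))
  invisible(NULL)
}
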