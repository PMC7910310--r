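# Pole recognition and quantitative polarisation measures.

#' Detect poles in a surface field
#'
#' Empirical pole recognition: vertices with
#' `u >= u_min + theta * (u_max - u_min)` form the candidate set; connected
#' components of the candidate set under mesh adjacency are poles;
#' components covering less than `min_area_frac` of the surface are
#' discarded as noise. The relative pole area is the summed lumped vertex
#' area of all retained components divided by the total surface area. A
#' constant field has no poles by definition, and the rule is invariant
#' under affine rescaling of the field.
#'
#' @param u_field vertex field on `mesh`.
#' @param mesh a [build_icosphere()] mesh.
#' @param theta threshold fraction of the field range, in (0, 1);
#'   default 0.5 (midrange).
#' @param min_area_frac minimal relative component area retained
#'   (default 0.01).
#' @return List with `count`, `relative_area`, `labels` (integer vector,
#'   0 for vertices outside any pole, 1..count otherwise) and
#'   `component_areas`.
#' @examples
#' mesh <- build_icosphere(3)
#' cap <- as.numeric(mesh$vertices[, 3] > 0.5)  # polar cap indicator
#' detect_poles(cap, mesh)$count
#' @export
detect_poles <- function(u_field, mesh, theta = 0.5, min_area_frac = 0.01) {
  stopifnot(length(u_field) == mesh$n_vertices, theta > 0, theta < 1)
  rng <- range(u_field)
  labels <- integer(mesh$n_vertices)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    return(list(count = 0L, relative_area = 0, labels = labels,
                component_areas = numeric(0)))
  }
  cand <- u_field >= rng[1] + theta * diff(rng)
  idx <- which(cand)
  e <- mesh$edges
  both <- cand[e[, 1]] & cand[e[, 2]]
  g <- igraph::graph_from_edgelist(
    rbind(e[both, , drop = FALSE], cbind(idx, idx)), directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership[idx]
  areas <- tapply(mesh$areas[idx], memb, sum)
  keep <- names(areas)[areas >= min_area_frac * mesh$surface_area]
  areas <- areas[keep]
  if (!length(areas)) {
    return(list(count = 0L, relative_area = 0, labels = labels,
                component_areas = numeric(0)))
  }
  ord <- order(areas, decreasing = TRUE)
  relabel <- stats::setNames(seq_along(ord), names(areas)[ord])
  inkeep <- as.character(memb) %in% keep
  labels[idx[inkeep]] <- relabel[as.character(memb[inkeep])]
  list(count = length(areas),
       relative_area = as.numeric(sum(areas)) / mesh$surface_area,
       labels = labels,
       component_areas = as.numeric(areas[ord]))
}

#' Quantitative polarisation report for a finished run
#'
#' Extracts the quantitative polarisation measures at the final time of a
#' simulation: pole count and relative pole area (from [detect_poles()] on
#' the final active-form field), the vertex-wise maximum and minimum of
#' `u`, and the termination time `tau_final`.
#'
#' @param traj a `cdc42_trajectory` from [simulate_to_polarisation()].
#' @param mesh the mesh the trajectory was run on; rebuilt from the
#'   recorded level when omitted.
#' @return An object of class `cdc42_pole_report`: list with `pole_count`,
#'   `relative_pole_area`, `u_max`, `u_min`, `tau_final`, `termination`,
#'   `seed` and the parameter snapshot.
#' @export
pole_report <- function(traj, mesh = NULL) {
  stopifnot(inherits(traj, "cdc42_trajectory"))
  if (is.null(mesh)) mesh <- build_icosphere(traj$mesh_level)
  poles <- detect_poles(traj$u, mesh, theta = traj$opts$theta,
                        min_area_frac = traj$opts$min_pole_area)
  structure(
    list(pole_count = poles$count,
         relative_pole_area = poles$relative_area,
         u_max = max(traj$u), u_min = min(traj$u),
         tau_final = traj$tau_final, termination = traj$termination,
         seed = traj$seed, params = traj$params),
    class = "cdc42_pole_report")
}

#' @export
print.cdc42_pole_report <- function(x, ...) {
  cat(sprintf(
    "Pole report: %d pole(s), %.1f%% of the surface, u in [%.3f, %.3f], tau_final = %.3f (%s)\n",
    x$pole_count, 100 * x$relative_pole_area, x$u_min, x$u_max,
    x$tau_final, x$termination))
  invisible(x)
}

#' Deterministic per-run seed for sweeps
#'
#' Derives a reproducible RNG seed from the base seed, the swept parameter
#' value and the replicate index, kept within the 32-bit integer range.
#'
#' @param base_seed integer base seed.
#' @param value swept parameter value.
#' @param replicate replicate index (1-based).
#' @return An integer seed.
#' @export
derive_seed <- function(base_seed, value, replicate) {
  v <- as.integer(round(value * 1e4)) %% 65521L
  s <- (as.integer(base_seed) %% 2147483L) * 1000L
  as.integer((s + v * 131L + replicate * 7919L) %% 2147483647L) + 1L
}

#' Multi-seed sweep over a model parameter
#'
#' Runs [simulate_to_polarisation()] for each value of a swept parameter
#' (typically `d` or `gamma`) and each of `n_seeds` replicates, and
#' tabulates the 5%/50%/95% quantiles of the polarisation measures per
#' value. Per-run seeds are derived deterministically from `base_seed` via
#' [derive_seed()], so the whole sweep is reproducible. Individual run
#' failures are recorded and excluded from the quantiles.
#'
#' @param name swept parameter name (one of the [model_params()] fields,
#'   usually `"d"` or `"gamma"`).
#' @param values sorted numeric vector of parameter values.
#' @param params base parameter set.
#' @param n_seeds replicates per value (the reference study used 20).
#' @param base_seed base RNG seed.
#' @param opts base [sim_options()]; the per-run seed overrides its `seed`.
#' @param mesh optional shared mesh.
#' @return An object of class `cdc42_sweep`: list with `name`, `values`,
#'   `reports` (data.frame of all runs), `quantiles` (long data.frame:
#'   value, measure, q5, q50, q95) and `n_failed`.
#' @export
sweep_parameter <- function(name, values, params, n_seeds = 20,
                            base_seed = 1L, opts = sim_options(),
                            mesh = NULL) {
  stopifnot(name %in% c("c1", "c_minus1", "c2", "c_max", "V0", "gamma", "d"),
            n_seeds >= 1, !is.unsorted(values))
  if (is.null(mesh)) mesh <- build_icosphere(opts$subdivisions)
  rows <- list()
  n_failed <- 0L
  for (val in values) {
    p <- do.call(update_params, stats::setNames(list(params, val),
                                                c("", name)))
    for (r in seq_len(n_seeds)) {
      o <- opts
      o$seed <- derive_seed(base_seed, val, r)
      rep_i <- tryCatch({
        traj <- simulate_to_polarisation(p, o, mesh = mesh)
        pr <- pole_report(traj, mesh)
        data.frame(value = val, replicate = r, seed = o$seed,
                   pole_count = pr$pole_count,
                   relative_pole_area = pr$relative_pole_area,
                   u_max = pr$u_max, u_min = pr$u_min,
                   tau_final = pr$tau_final, termination = pr$termination)
      }, error = function(e) {
        message("sweep run failed (", name, " = ", val, ", replicate ", r,
                "): ", conditionMessage(e))
        NULL
      })
      if (is.null(rep_i)) n_failed <- n_failed + 1L else {
        rows[[length(rows) + 1]] <- rep_i
      }
    }
  }
  reports <- do.call(rbind, rows)
  measures <- c("pole_count", "relative_pole_area", "u_max", "u_min",
                "tau_final")
  qs <- do.call(rbind, lapply(unique(reports$value), function(val) {
    sub <- reports[reports$value == val, ]
    do.call(rbind, lapply(measures, function(mm) {
      q <- stats::quantile(sub[[mm]], c(0.05, 0.5, 0.95), names = FALSE)
      data.frame(value = val, measure = mm, q5 = q[1], q50 = q[2], q95 = q[3])
    }))
  }))
  structure(list(name = name, values = values, reports = reports,
                 quantiles = qs, n_failed = n_failed,
                 base_seed = base_seed, n_seeds = n_seeds),
            class = "cdc42_sweep")
}

#' @export
print.cdc42_sweep <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values x %d seeds, %d failed)\n",
              x$name, length(x$values), x$n_seeds, x$n_failed))
  med <- x$quantiles[x$quantiles$measure %in%
                       c("pole_count", "relative_pole_area", "u_max"), ]
  print(stats::reshape(med[, c("value", "measure", "q50")],
                       direction = "wide", idvar = "value",
                       timevar = "measure"), row.names = FALSE)
  invisible(x)
}

#' Write sweep results to CSV and JSON
#'
#' @param sweep a `cdc42_sweep`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_sweep <- function(sweep, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(sweep$reports, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(name = sweep$name, values = sweep$values,
           base_seed = sweep$base_seed, n_seeds = sweep$n_seeds,
           reports = sweep$reports, quantiles = sweep$quantiles),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' Quantile plot of a sweep measure
#'
#' Plots the 5/50/95% quantile band of one polarisation measure against
#' the swept parameter (median solid, outer quantiles dashed), mirroring
#' the style of multi-realisation sweep figures.
#'
#' @param sweep a `cdc42_sweep`.
#' @param measure one of `"pole_count"`, `"relative_pole_area"`, `"u_max"`,
#'   `"u_min"`, `"tau_final"`.
#' @param file optional PNG path.
#' @return The ggplot object (or `NULL` with base graphics), invisibly.
#' @export
plot_sweep <- function(sweep, measure = "relative_pole_area", file = NULL) {
  q <- sweep$quantiles[sweep$quantiles$measure == measure, ]
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    p <- ggplot2::ggplot(q, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$q50)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$q5), linetype = "dashed") +
      ggplot2::geom_line(ggplot2::aes(y = .data$q95), linetype = "dashed") +
      ggplot2::labs(x = sweep$name, y = measure) +
      ggplot2::theme_minimal()
    if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 4,
                                        dpi = 150)
    return(invisible(p))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 750, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(q$value, q$q50, type = "l", xlab = sweep$name,
                 ylab = measure, ylim = range(q[, c("q5", "q95")]))
  graphics::lines(q$value, q$q5, lty = 2)
  graphics::lines(q$value, q$q95, lty = 2)
  invisible(NULL)
}
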