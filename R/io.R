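# Plain-text configuration, VTK field export and tabular writers.

#' Read model parameters from a flat key-value config file
#'
#' Parses a plain-text file with one `key = value` pair per line (`#`
#' starts a comment). Recognised keys are exactly the [model_params()]
#' fields: `c1`, `c_minus1`, `c2`, `c_max`, `V0`, `gamma`, `d`, `a`.
#' Missing keys fall back to the [model_params()] defaults; unknown keys
#' are an error.
#'
#' @param path config file path.
#' @param defaults a `cdc42_params` supplying values for absent keys.
#' @return A `cdc42_params` object.
#' @export
read_params_config <- function(path, defaults = model_params(
                                 c1 = 0.05, c_minus1 = 0.04, c2 = 0.45)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("unparsable config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2))))
  allowed <- c("c1", "c_minus1", "c2", "c_max", "V0", "gamma", "d", "a")
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("non-numeric config value(s) for: ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  args <- defaults[allowed]
  args[keys] <- vals
  do.call(model_params, args)
}

#' Write surface fields as a legacy VTK polydata file
#'
#' Writes the mesh and the `u`, `v` point-data arrays as ASCII legacy VTK
#' (POLYDATA), readable by common visualisers. The round trip through
#' [read_fields_vtk()] preserves vertex count and field values to printed
#' precision.
#'
#' @param path output file path.
#' @param mesh a [build_icosphere()] mesh.
#' @param fields a `cdc42_fields` list (uses `u` and `v`).
#' @return `path`, invisibly.
#' @export
write_fields_vtk <- function(path, mesh, fields) {
  stopifnot(length(fields$u) == mesh$n_vertices,
            length(fields$v) == mesh$n_vertices)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  writeLines(c("# vtk DataFile Version 3.0",
               "cdc42sim surface fields", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", mesh$n_vertices, "double")), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(fmt(r), collapse = " ")),
             con)
  nf <- nrow(mesh$faces)
  writeLines(paste("POLYGONS", nf, 4 * nf), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  writeLines(paste("POINT_DATA", mesh$n_vertices), con)
  for (nm in c("u", "v")) {
    writeLines(c(paste("SCALARS", nm, "double", 1),
                 "LOOKUP_TABLE default"), con)
    writeLines(fmt(fields[[nm]]), con)
  }
  invisible(path)
}

#' Read surface fields back from a legacy VTK polydata file
#'
#' Companion reader for [write_fields_vtk()].
#'
#' @param path VTK file path.
#' @return List with `vertices`, `faces` and the point-data fields (`u`,
#'   `v`).
#' @export
read_fields_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  np <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE)[1],
                            "\\s+")[[1]][2])
  ip <- grep("^POINTS", lines)[1]
  vertices <- do.call(rbind, lapply(lines[(ip + 1):(ip + np)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  ipoly <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(lines[ipoly], "\\s+")[[1]][2])
  faces <- do.call(rbind, lapply(lines[(ipoly + 1):(ipoly + nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]][-1]) + 1L))
  out <- list(vertices = vertices, faces = faces)
  for (isc in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[isc], "\\s+")[[1]][2]
    out[[nm]] <- as.numeric(lines[(isc + 2):(isc + 1 + np)])
  }
  out
}

#' Write a trajectory summary as CSV
#'
#' Writes the per-record summary (`tau`, `mass`, `u_max`, `u_min`,
#' `pole_count`, `pole_area`) of a simulation.
#'
#' @param traj a `cdc42_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_summary <- function(traj, path) {
  utils::write.csv(traj$summary, path, row.names = FALSE)
  invisible(path)
}
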