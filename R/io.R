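## Plain-text mesh and report writers (ASCII STL, legacy VTK, JSON).
## Minimal writers; headers state units and index conventions.

#' Write a triangle mesh as ASCII STL
#' @param mesh list with `vertices`, triangle `faces`.
#' @param path output file; `name` solid name.
#' @export
write_stl <- function(mesh, path, name = "surface") {
  v <- mesh$vertices; f <- mesh$faces
  n <- tri_centers_normals(mesh)$normals
  n <- n / pmax(row_norms(n), 1e-12)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %.8g %.8g %.8g", n[i, 1], n[i, 2], n[i, 3]),
      "    outer loop",
      sprintf("      vertex %.8g %.8g %.8g",
              v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
      "    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Write a structured surface (plus point-data fields) as legacy VTK
#'
#' Quad polydata; point data arrays are per structured node (layer-major,
#' 1-based layers/nodes in the header comment). Units belong in the field
#' names (e.g. `stress_kpa`, `growth_pct_per_year`).
#' @param structured a `structured_surface`.
#' @param path output file.
#' @param point_data named list of n_layers x n_nodes matrices.
#' @export
write_vtk_surface <- function(structured, path, point_data = list()) {
  nl <- structured$n_layers; nn <- structured$n_nodes
  pts <- matrix(aperm(structured$nodes, c(2, 1, 3)), nl * nn, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "structured aortic surface; layers x nodes, 1-based, mm",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  write(t(pts), con, ncolumns = 3)
  vid <- function(i, j) (i - 1L) * nn + ((j - 1L) %% nn) + 1L
  quads <- do.call(rbind, lapply(seq_len(nl - 1L), function(i) {
    j <- seq_len(nn)
    cbind(4L, vid(i, j) - 1L, vid(i, j + 1L) - 1L,
          vid(i + 1L, j + 1L) - 1L, vid(i + 1L, j) - 1L)
  }))
  writeLines(sprintf("POLYGONS %d %d", nrow(quads), 5L * nrow(quads)), con)
  write(t(quads), con, ncolumns = 5)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      vals <- as.vector(t(point_data[[nm]]))
      vals[!is.finite(vals)] <- -1e30
      write(vals, con, ncolumns = 9)
    }
  }
  invisible(path)
}

#' Write a hex solid mesh as legacy VTK unstructured grid
#' @param solid a `solid_mesh`; `path` output; `cell_data` named list of
#'   per-element vectors; `point_data` named list of per-node vectors.
#' @export
write_vtk_solid <- function(solid, path, cell_data = list(),
                            point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(solid$nodes); ne <- nrow(solid$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "hex wall mesh; coordinates mm; stresses kPa",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", np)), con)
  write(t(solid$nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", ne, 9L * ne), con)
  write(t(cbind(8L, solid$elems - 1L)), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  write(rep(12L, ne), con, ncolumns = 20)  # VTK_HEXAHEDRON
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      write(cell_data[[nm]], con, ncolumns = 9)
    }
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", np), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      write(point_data[[nm]], con, ncolumns = 9)
    }
  }
  invisible(path)
}

#' Write a region partition as JSON (1-based layer ranges)
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(
    list(convention = "1-based layer indices, inclusive ranges",
         regions = as.data.frame(partition)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a mixed-model fit report as JSON
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(fixed_effects = fit$beta,
         random_effect_sd = list(intercept = fit$sd_b0, slope = fit$sd_b1,
                                 residual = fit$sd_eps),
         F_test = list(F = fit$F, p = fit$p, df_method = fit$df_method),
         logLik = fit$logLik, AIC = fit$AIC, BIC = fit$BIC,
         n_obs = fit$n_obs, n_patients = fit$n_patients,
         singular = fit$singular,
         fixed_only_slope = unname(fit$fixed_only$beta["x"])),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
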