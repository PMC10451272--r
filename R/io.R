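#' Write a grid and cell fields as a legacy VTK rectilinear file
#'
#' Minimal ASCII writer (legacy `RECTILINEAR_GRID` format, cell data) for
#' visualizing masks, velocity magnitude, pressure, viscosity, fluence or
#' temperature in ParaView-compatible tools.
#'
#' @param grid a [build_grid()] result.
#' @param fields named list of numeric 3D arrays on the grid (cell-centred).
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(grid, fields, file) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  xf <- grid$x0 + (0:nx) * grid$dx
  yf <- grid$y0 + (0:ny) * grid$dy
  zf <- grid$zf
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("photoecmo structured grid export")
  w("ASCII")
  w("DATASET RECTILINEAR_GRID")
  w("DIMENSIONS ", nx + 1, " ", ny + 1, " ", nz + 1)
  w("X_COORDINATES ", nx + 1, " float")
  w(paste(format(xf, trim = TRUE), collapse = " "))
  w("Y_COORDINATES ", ny + 1, " float")
  w(paste(format(yf, trim = TRUE), collapse = " "))
  w("Z_COORDINATES ", nz + 1, " float")
  w(paste(format(zf, trim = TRUE), collapse = " "))
  w("CELL_DATA ", nx * ny * nz)
  for (nm in names(fields)) {
    arr <- fields[[nm]]
    stopifnot(all(dim(arr) == c(nx, ny, nz)))
    w("SCALARS ", nm, " float 1")
    w("LOOKUP_TABLE default")
    vals <- as.vector(arr)            # x fastest, matching VTK ordering
    vals[!is.finite(vals)] <- 0
    writeLines(paste(format(vals, trim = TRUE, digits = 7)), con)
  }
  invisible(file)
}

#' Serialize a device spec to YAML
#'
#' @param spec a [device_spec()].
#' @param file output path (`NULL` returns the YAML string).
#' @return file path or YAML string.
#' @export
write_device_yaml <- function(spec, file = NULL) {
  txt <- yaml::as.yaml(unclass(spec))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Read a device spec from YAML
#'
#' @param file YAML path (e.g. one of the shipped presets under
#'   `system.file("extdata", package = "photoecmo")`).
#' @return a [device_spec()].
#' @export
read_device_yaml <- function(file) {
  v <- yaml::read_yaml(file)
  do.call(device_spec, v[setdiff(names(v), c("inlet_face", "outlet_face"))])
}

# polynomial rolling hash of a serialized R object (deterministic provenance
# tag; arithmetic kept below 2^53 so the result is exact in doubles)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  p <- 2147483647
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% p
    h2 <- (h2 * 131 + b) %% p
  }
  sprintf("%08x%08x", h1, h2)
}
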