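#' Parametric photo-ECMO device geometry
#'
#' A `device_spec` describes one filleted-square blood chamber: a
#' `chamber_length` x `chamber_width` x `chamber_height` cm slab whose four
#' corners are rounded with circular fillets of radius `fillet_radius`,
#' enclosed in a plexiglass casing, with an inlet tube on the bottom face and
#' an outlet tube on the top face at diagonally opposite corners.
#'
#' Port placement follows the device convention: for a square chamber the
#' ports sit `port_inset` cm from each adjacent edge; when fillets are added
#' the inset grows by `fillet_radius * port_scaling_factor` along each edge so
#' the port clears the corner arc.
#'
#' @param fillet_radius corner fillet radius in cm (0 for the plain square).
#' @param chamber_length,chamber_width,chamber_height chamber dimensions, cm.
#' @param plexiglass_thickness casing wall thickness, cm (applied to all faces).
#' @param tube_inner_diameter,tube_outer_diameter inlet/outlet tube bore and
#'   outer diameter, cm. The default bore of 1.27 cm is the value consistent
#'   with the device's reported mean tube velocities (flow rate / bore area);
#'   see the methods vignette for the alternative 0.635 cm reading.
#' @param tube_height tube stub height above the outer plexiglass surface, cm.
#' @param port_inset base distance of each port centre from the two adjacent
#'   chamber edges, cm.
#' @param port_scaling_factor dimensionless factor multiplying the fillet
#'   radius when shifting ports inward along each edge.
#' @return an object of class `device_spec`.
#' @examples
#' g1 <- device_spec(0)
#' g2 <- device_spec(5)
#' footprint_area(g2)
#' @export
device_spec <- function(fillet_radius = 0,
                        chamber_length = 20, chamber_width = 20,
                        chamber_height = 1,
                        plexiglass_thickness = 1.1,
                        tube_inner_diameter = 1.27,
                        tube_outer_diameter = tube_inner_diameter + 0.04,
                        tube_height = 1.4,
                        port_inset = 1.2,
                        port_scaling_factor = 0.3) {
  spec <- structure(list(
    fillet_radius = fillet_radius,
    chamber_length = chamber_length,
    chamber_width = chamber_width,
    chamber_height = chamber_height,
    plexiglass_thickness = plexiglass_thickness,
    tube_inner_diameter = tube_inner_diameter,
    tube_outer_diameter = tube_outer_diameter,
    tube_height = tube_height,
    port_inset = port_inset,
    port_scaling_factor = port_scaling_factor,
    inlet_face = "bottom", outlet_face = "top"
  ), class = "device_spec")
  validate_device_spec(spec)
  spec
}

validate_device_spec <- function(spec) {
  dims <- c("chamber_length", "chamber_width", "chamber_height",
            "plexiglass_thickness", "tube_inner_diameter", "tube_height")
  for (d in dims) {
    if (!is.numeric(spec[[d]]) || spec[[d]] <= 0)
      stop("invalid-geometry: ", d, " must be > 0", call. = FALSE)
  }
  r <- spec$fillet_radius
  if (r < 0 || r > min(spec$chamber_length, spec$chamber_width) / 2)
    stop("invalid-geometry: fillet_radius must lie in [0, min(L, W)/2]",
         call. = FALSE)
  # ports (including the tube bore) must sit strictly inside the footprint
  pp <- port_positions(spec, check = FALSE)
  rad <- spec$tube_inner_diameter / 2
  sd <- footprint_sdf(spec, c(pp$inlet[1], pp$outlet[1]),
                      c(pp$inlet[2], pp$outlet[2]))
  if (any(sd > -rad))
    stop("invalid-geometry: port disc extends outside the filleted footprint",
         call. = FALSE)
  invisible(spec)
}

#' Three shipped device presets
#'
#' Geometry 1 is the plain 20 x 20 x 1 cm square chamber; Geometries 2 and 3
#' carry 5 cm and 10 cm corner fillets.
#'
#' @param geometry integer 1, 2 or 3.
#' @param ... overrides passed on to [device_spec()].
#' @return a `device_spec`.
#' @export
device_preset <- function(geometry, ...) {
  r <- switch(as.character(geometry), "1" = 0, "2" = 5, "3" = 10,
              stop("geometry must be 1, 2 or 3"))
  device_spec(fillet_radius = r, ...)
}

#' Hollow-fiber mat specification
#'
#' Describes the stacked gas-exchange mats (microporous polypropylene hollow
#' fibers, 280 um lumen + 2 x 50 um wall giving a 380 um outer diameter)
#' used for priming-volume accounting. Fibers are not resolved by any solver.
#'
#' @param fibers_per_cm linear fiber density along the mat, fibers per cm of
#'   width (default 20, i.e. 20 fibers per 10 mm).
#' @param n_layers number of stacked mats.
#' @param fiber_outer_diameter fiber outer diameter, cm.
#' @return an object of class `fiber_mat_spec`.
#' @export
fiber_mat_spec <- function(fibers_per_cm = 20, n_layers = 20,
                           fiber_outer_diameter = 0.038) {
  stopifnot(fibers_per_cm > 0, n_layers >= 0, fiber_outer_diameter > 0)
  structure(list(fibers_per_cm = fibers_per_cm, n_layers = n_layers,
                 fiber_outer_diameter = fiber_outer_diameter),
            class = "fiber_mat_spec")
}

#' Footprint area of the filleted chamber
#'
#' Closed form: `L * W - (4 - pi) * r^2` for a rectangle with four equal
#' corner fillets of radius `r`.
#'
#' @param spec a [device_spec()].
#' @return area in cm^2.
#' @export
footprint_area <- function(spec) {
  validate_device_spec(spec)
  spec$chamber_length * spec$chamber_width - (4 - pi) * spec$fillet_radius^2
}

#' Signed distance to the filleted footprint boundary
#'
#' Negative inside the footprint, positive outside (rounded-rectangle signed
#' distance in the chamber plane; vectorized over points).
#'
#' @param spec a [device_spec()].
#' @param x,y point coordinates, cm.
#' @return signed distance, cm.
#' @export
footprint_sdf <- function(spec, x, y) {
  r <- spec$fillet_radius
  hx <- spec$chamber_length / 2
  hy <- spec$chamber_width / 2
  qx <- abs(x - hx) - (hx - r)
  qy <- abs(y - hy) - (hy - r)
  mx <- pmax(qx, 0); my <- pmax(qy, 0)
  sqrt(mx^2 + my^2) + pmin(pmax(qx, qy), 0) - r
}

#' @rdname footprint_sdf
#' @export
in_footprint <- function(spec, x, y) footprint_sdf(spec, x, y) < 0

#' Priming (blood) volume of the chamber
#'
#' Without fiber mats the priming volume is footprint area times chamber
#' height. With mats, the solid fiber volume is subtracted: total fiber
#' length per layer is taken as linear density x footprint area (each layer
#' covers the footprint with parallel fibers), or, with `method = "chords"`,
#' as the sum of exact chord lengths of the filleted footprint at each fiber
#' position.
#'
#' @param spec a [device_spec()].
#' @param fibers a [fiber_mat_spec()] or `NULL` for the bare chamber.
#' @param method `"area"` (linear density x area) or `"chords"` (exact chord
#'   summation).
#' @return blood volume in cm^3.
#' @export
priming_volume <- function(spec, fibers = NULL, method = c("area", "chords")) {
  method <- match.arg(method)
  area <- footprint_area(spec)
  vol <- area * spec$chamber_height
  if (is.null(fibers)) return(vol)
  stopifnot(inherits(fibers, "fiber_mat_spec"))
  a_f <- pi * (fibers$fiber_outer_diameter / 2)^2
  len_per_layer <- if (method == "area") {
    fibers$fibers_per_cm * area
  } else {
    spacing <- 1 / fibers$fibers_per_cm
    ypos <- seq(spacing / 2, spec$chamber_width - spacing / 2, by = spacing)
    sum(vapply(ypos, function(y) footprint_chord(spec, y), numeric(1)))
  }
  fiber_vol <- len_per_layer * a_f * fibers$n_layers
  if (fiber_vol >= vol)
    stop("invalid-geometry: fiber solid volume exceeds chamber volume",
         call. = FALSE)
  vol - fiber_vol
}

# chord length of the filleted footprint at height y (x-measure of the slice)
footprint_chord <- function(spec, y) {
  r <- spec$fillet_radius
  L <- spec$chamber_length; W <- spec$chamber_width
  if (y <= 0 || y >= W) return(0)
  d <- min(y, W - y)                 # distance to the nearer long edge
  if (d >= r) return(L)
  cut <- r - sqrt(r^2 - (r - d)^2)   # per-corner x-recess at this height
  L - 2 * cut
}

#' Inlet and outlet port positions
#'
#' The inlet sits on the bottom face near one corner, the outlet on the top
#' face near the diagonally opposite corner. For fillet radius `r` the inset
#' from each adjacent edge is `port_inset + r * port_scaling_factor`.
#'
#' @param spec a [device_spec()].
#' @param check validate that the full port disc lies inside the footprint.
#' @return list with `inlet` and `outlet`, each an `(x, y)` pair in cm.
#' @export
port_positions <- function(spec, check = TRUE) {
  a <- spec$port_inset + spec$fillet_radius * spec$port_scaling_factor
  pos <- list(inlet = c(x = a, y = a),
              outlet = c(x = spec$chamber_length - a,
                         y = spec$chamber_width - a))
  if (check) {
    rad <- spec$tube_inner_diameter / 2
    sd <- footprint_sdf(spec, c(pos$inlet[1], pos$outlet[1]),
                        c(pos$inlet[2], pos$outlet[2]))
    if (any(sd > -rad))
      stop("invalid-geometry: port disc extends outside the filleted footprint",
           call. = FALSE)
  }
  pos
}

#' Structured computational grid with material mask
#'
#' Builds a cell-centered Cartesian grid covering the blood chamber and
#' (optionally) the plexiglass shell. Cells are classified by their centre:
#' `1` blood (inside the filleted footprint, within the chamber thickness),
#' `2` plexiglass (within `plexiglass_thickness` of the chamber on any side),
#' `0` outside. The z axis runs through the thickness; indices are 1-based
#' with the chamber corner at the coordinate origin.
#'
#' @param spec a [device_spec()].
#' @param resolution in-plane cells per cm (>= 1; the chamber thickness gets
#'   at least `nz_blood` cells regardless).
#' @param nz_blood number of cell layers through the blood thickness
#'   (default `max(2, ceiling(chamber_height * resolution))`).
#' @param include_shell include the plexiglass casing in the grid.
#' @param nz_shell number of cell layers through each plexiglass window
#'   (only when `include_shell = TRUE`).
#' @return an object of class `pe_grid` with face/centre coordinates, cell
#'   sizes, the material `mask` array and bookkeeping fields.
#' @export
build_grid <- function(spec, resolution = 2, nz_blood = NULL,
                       include_shell = TRUE, nz_shell = 3) {
  validate_device_spec(spec)
  if (resolution < 2 / spec$chamber_height && is.null(nz_blood))
    message("resolution gives < 2 cells through thickness; raising nz_blood")
  dx <- 1 / resolution
  if (is.null(nz_blood)) nz_blood <- max(2L, ceiling(spec$chamber_height * resolution))
  t <- if (include_shell) spec$plexiglass_thickness else 0
  m <- if (include_shell) ceiling(t / dx) else 0L   # margin cells per side
  nx <- ceiling(spec$chamber_length * resolution) + 2L * m
  ny <- ceiling(spec$chamber_width * resolution) + 2L * m
  x0 <- -m * dx; y0 <- -m * dx
  dzb <- spec$chamber_height / nz_blood
  if (include_shell) {
    dzs <- t / nz_shell
    zf <- c(seq(-t, 0, by = dzs),
            seq(dzb, spec$chamber_height, by = dzb),
            spec$chamber_height + seq_len(nz_shell) * dzs)
  } else {
    zf <- seq(0, spec$chamber_height, by = dzb)
  }
  nz <- length(zf) - 1L
  xc <- x0 + (seq_len(nx) - 0.5) * dx
  yc <- y0 + (seq_len(ny) - 0.5) * dx
  zc <- (zf[-1] + zf[-(nz + 1)]) / 2
  dzc <- diff(zf)
  sd <- outer(xc, yc, function(x, y) footprint_sdf(spec, x, y))
  mask <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    zk <- zc[k]
    in_blood_z <- zk > 0 && zk < spec$chamber_height
    if (in_blood_z) {
      mask[, , k] <- ifelse(sd < 0, 1L, ifelse(sd < t, 2L, 0L))
    } else if (include_shell && zk > -t && zk < spec$chamber_height + t) {
      mask[, , k] <- ifelse(sd < t, 2L, 0L)
    }
  }
  # warn when the tube bore is unresolved in-plane: ports become patch BCs
  if (spec$tube_inner_diameter < 2 * dx)
    warning("in-plane resolution does not resolve the tube diameter; ",
            "ports are represented as patch boundary conditions")
  structure(list(
    spec = spec, resolution = resolution,
    nx = nx, ny = ny, nz = nz, dx = dx, dy = dx,
    x0 = x0, y0 = y0, xc = xc, yc = yc, zc = zc, zf = zf, dzc = dzc,
    nz_blood = as.integer(nz_blood),
    kz_blood = which(zc > 0 & zc < spec$chamber_height),
    include_shell = include_shell,
    mask = mask, sdf2d = sd
  ), class = "pe_grid")
}

#' Blood volume captured by a grid
#'
#' Sum of the volumes of blood-masked cells; converges (first order in cell
#' size) to `footprint_area(spec) * chamber_height`.
#'
#' @param grid a [build_grid()] result.
#' @return volume in cm^3.
#' @export
grid_blood_volume <- function(grid) {
  v <- 0
  for (k in seq_len(grid$nz)) {
    v <- v + sum(grid$mask[, , k] == 1L) * grid$dx * grid$dy * grid$dzc[k]
  }
  v
}

#' Fractional overlap of a port disc with grid columns
#'
#' Used to distribute the inlet/outlet volumetric flux over the cells of a
#' patch boundary. Overlap fractions are estimated by 4x4 subsampling of each
#' cell and normalized so that they sum to the disc area.
#'
#' @param grid a [build_grid()] result (or any object with `xc`, `yc`, `dx`).
#' @param centre `(x, y)` port centre, cm.
#' @param radius port radius, cm.
#' @return data.frame with columns `i`, `j`, `frac` (fraction of the disc
#'   area assigned to that column).
#' @keywords internal
port_patch <- function(grid, centre, radius) {
  dx <- grid$dx
  ii <- which(abs(grid$xc - centre[1]) < radius + dx)
  jj <- which(abs(grid$yc - centre[2]) < radius + dx)
  sub <- (seq_len(4) - 2.5) / 4 * dx
  out <- expand.grid(i = ii, j = jj)
  fr <- mapply(function(i, j) {
    px <- grid$xc[i] + sub; py <- grid$yc[j] + sub
    g <- expand.grid(px = px, py = py)
    mean((g$px - centre[1])^2 + (g$py - centre[2])^2 < radius^2)
  }, out$i, out$j)
  out$area <- fr * dx * grid$dy
  out <- out[out$area > 0, , drop = FALSE]
  out$frac <- out$area / sum(out$area)
  out
}
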