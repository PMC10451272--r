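#' Release positions across the inlet cross-section
#'
#' @param field a [solve_flow()] result (provides the inlet location), or a
#'   `device_spec`.
#' @param n number of particles.
#' @param scheme `"random_uniform"` (uniform over the inlet disc) or
#'   `"uniform_grid"` (deterministic sunflower spiral; `n = 1` gives the
#'   inlet centre).
#' @param seed RNG seed (used by `"random_uniform"`).
#' @return matrix with columns `x`, `y`, `z` (cm), on the inlet face.
#' @export
release_positions <- function(field, n = 100,
                              scheme = c("random_uniform", "uniform_grid"),
                              seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1)
  spec <- if (inherits(field, "device_spec")) field else field$spec
  pp <- port_positions(spec)
  R <- spec$tube_inner_diameter / 2
  if (scheme == "random_uniform") {
    set.seed(seed)
    r <- R * sqrt(stats::runif(n))
    th <- 2 * pi * stats::runif(n)
  } else {
    i <- seq_len(n) - 1
    r <- R * sqrt(i / n)
    th <- i * pi * (3 - sqrt(5))
  }
  cbind(x = pp$inlet[1] + r * cos(th), y = pp$inlet[2] + r * sin(th),
        z = 0)
}

# trilinear interpolation on a uniform grid; coords of first node x0 etc.
trilin <- function(arr, x0, y0, z0, dx, dy, dz, px, py, pz) {
  d <- dim(arr)
  fx <- (px - x0) / dx; fy <- (py - y0) / dy; fz <- (pz - z0) / dz
  ix <- pmin(pmax(floor(fx) + 1, 1), d[1] - 1)
  iy <- pmin(pmax(floor(fy) + 1, 1), d[2] - 1)
  iz <- pmin(pmax(floor(fz) + 1, 1), d[3] - 1)
  tx <- pmin(pmax(fx - (ix - 1), 0), 1)
  ty <- pmin(pmax(fy - (iy - 1), 0), 1)
  tz <- pmin(pmax(fz - (iz - 1), 0), 1)
  g <- function(i, j, k) arr[cbind(i, j, k)]
  (1 - tz) * ((1 - ty) * ((1 - tx) * g(ix, iy, iz) + tx * g(ix + 1, iy, iz)) +
              ty * ((1 - tx) * g(ix, iy + 1, iz) + tx * g(ix + 1, iy + 1, iz))) +
  tz * ((1 - ty) * ((1 - tx) * g(ix, iy, iz + 1) + tx * g(ix + 1, iy, iz + 1)) +
        ty * ((1 - tx) * g(ix, iy + 1, iz + 1) + tx * g(ix + 1, iy + 1, iz + 1)))
}

# velocity interpolator factory for a flow_field; positions in cm, output m/s
make_velocity_interp <- function(field) {
  g <- field$grid
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  dx <- g$dx; dzc <- g$dzc[1]
  M <- field$mask2d
  pad <- function(a) {
    p <- array(0, c(nx + 2, ny + 2, nz + 2))
    p[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] <- a
    # mirror across the z walls so the interpolated velocity vanishes there
    p[, , 1] <- -p[, , 2]; p[, , nz + 2] <- -p[, , nz + 1]
    p
  }
  zero_solid <- function(a) { # lateral non-blood cells already zero in Uc
    for (k in seq_len(nz)) a[, , k][!M] <- 0
    a
  }
  Up <- pad(zero_solid(field$Uc)); Vp <- pad(zero_solid(field$Vc))
  x0 <- g$xc[1] - dx; y0 <- g$yc[1] - dx; z0 <- g$zc[1] - dzc
  wfa <- field$w                      # (nx, ny, nz+1) at z faces
  function(px, py, pz) {
    cbind(
      trilin(Up, x0, y0, z0, dx, dx, dzc, px, py, pz),
      trilin(Vp, x0, y0, z0, dx, dx, dzc, px, py, pz),
      trilin(wfa, g$xc[1], g$yc[1], g$zf[1], dx, dx, dzc, px, py, pz))
  }
}

#' Lagrangian particle residence times
#'
#' Releases `n` particles simultaneously across the inlet and integrates
#' their trajectories through the steady flow field, recording the first
#' outlet-crossing time of each. By default particles are neutrally buoyant
#' erythrocyte-scale tracers whose drag relaxation time is far below the
#' flow time scale, so the integration follows streamlines (adaptive RK2
#' with a CFL-limited step); with `drag = "stokes"` the full
#' mass-plus-Stokes-drag equation is integrated with an exact exponential
#' update of the particle velocity per step. Deterministic given `seed`.
#'
#' @param field a converged [solve_flow()] result.
#' @param n number of particles.
#' @param duration_min simulated time horizon, minutes.
#' @param output_interval_min storage interval of the cumulative counts.
#' @param drag `"tracer"` or `"stokes"`.
#' @param diameter_um,density_kg_m3 particle diameter and density for the
#'   Stokes drag model.
#' @param scheme,seed release scheme and seed (see [release_positions()]).
#' @param cfl time-step fraction of a cell-crossing time.
#' @param dt_max maximum time step, s.
#' @param outlet_radius_factor particles crossing the top face within this
#'   multiple of the tube radius around the outlet centre count as arrived.
#' @return object of class `residence_table`: data.frame `minute`, `count`
#'   (cumulative arrivals), with arrival times, release metadata and the
#'   number of stuck particles as attributes.
#' @export
trace_particles <- function(field, n = 100, duration_min = 15,
                            output_interval_min = 1,
                            drag = c("tracer", "stokes"),
                            diameter_um = 8, density_kg_m3 = 1057,
                            scheme = "random_uniform", seed = 1,
                            cfl = 0.3, dt_max = 0.5,
                            outlet_radius_factor = 1.25) {
  drag <- match.arg(drag)
  stopifnot(n >= 1)
  spec <- field$spec
  g <- field$grid
  h <- spec$chamber_height
  pp <- port_positions(spec)
  r_out <- spec$tube_inner_diameter / 2 * outlet_radius_factor
  interp <- make_velocity_interp(field)
  pos <- release_positions(spec, n, scheme, seed)
  tcur <- numeric(n)
  arrival <- rep(NA_real_, n)
  status <- rep(0L, n)                 # 0 active, 1 arrived, 2 stuck
  vel <- interp(pos[, 1], pos[, 2], pos[, 3])   # release with field velocity
  still0 <- sqrt(rowSums(vel^2)) < 1e-10
  if (any(still0)) {
    warning(sum(still0), " particle(s) released in a zero-velocity cell; ",
            "marked stuck")
    status[still0] <- 2L
  }
  tau <- if (drag == "stokes") {
    mu_ref <- carreau_viscosity(100, field$rheology)
    density_kg_m3 * (diameter_um * 1e-6)^2 / (18 * mu_ref)
  } else 0
  dur_s <- duration_min * 60
  dx_m <- field$dx_m
  it <- 0L
  while (any(status == 0L) && it < 5e5) {
    it <- it + 1L
    a <- which(status == 0L)
    uf <- interp(pos[a, 1], pos[a, 2], pos[a, 3])
    spd <- sqrt(rowSums(uf^2))
    dt <- pmin(dt_max, cfl * dx_m / pmax(spd, 1e-12))
    dt <- pmin(dt, dur_s - tcur[a])
    if (drag == "tracer") {
      mid <- pos[a, , drop = FALSE] + 0.5 * dt * uf * 100
      mid[, 3] <- pmin(pmax(mid[, 3], 0), h)
      uf2 <- interp(mid[, 1], mid[, 2], mid[, 3])
      newp <- pos[a, , drop = FALSE] + dt * uf2 * 100
    } else {
      e <- exp(-dt / tau)
      vrel <- vel[a, , drop = FALSE] - uf
      newp <- pos[a, , drop = FALSE] +
        100 * (uf * dt + vrel * tau * (1 - e))
      vel[a, ] <- uf + vrel * e
    }
    oldz <- pos[a, 3]
    # outlet crossing through the top face near the outlet port
    hit <- newp[, 3] >= h &
      (newp[, 1] - pp$outlet[1])^2 + (newp[, 2] - pp$outlet[2])^2 < r_out^2
    frac <- ifelse(newp[, 3] > oldz, (h - oldz) / (newp[, 3] - oldz), 1)
    # reflect at the z walls (prevents spurious wall capture: a clamped
    # particle would sit exactly on the no-slip plane and never move again)
    newp[, 3] <- ifelse(newp[, 3] < 0, -newp[, 3], newp[, 3])
    newp[, 3] <- ifelse(newp[, 3] > h, 2 * h - newp[, 3], newp[, 3])
    newp[, 3] <- pmin(pmax(newp[, 3], 1e-6), h - 1e-6)
    # push particles that overshot the lateral wall back along the normal
    sd <- footprint_sdf(spec, newp[, 1], newp[, 2])
    outw <- sd > -1e-6
    if (any(outw)) {
      eps <- 1e-4
      gx <- (footprint_sdf(spec, newp[outw, 1] + eps, newp[outw, 2]) -
             footprint_sdf(spec, newp[outw, 1] - eps, newp[outw, 2])) / (2 * eps)
      gy <- (footprint_sdf(spec, newp[outw, 1], newp[outw, 2] + eps) -
             footprint_sdf(spec, newp[outw, 1], newp[outw, 2] - eps)) / (2 * eps)
      gn <- sqrt(gx^2 + gy^2); gn[gn == 0] <- 1
      push <- sd[outw] + 0.02       # land 0.02 cm inside the wall
      newp[outw, 1] <- newp[outw, 1] - push * gx / gn
      newp[outw, 2] <- newp[outw, 2] - push * gy / gn
    }
    if (any(!is.finite(newp)))
      stop("particle escaped the blood domain (numerical leak); ids: ",
           paste(a[!is.finite(rowSums(newp))], collapse = ", "))
    pos[a, ] <- newp
    tcur[a] <- tcur[a] + dt
    if (any(hit)) {
      ida <- a[hit]
      arrival[ida] <- (tcur[ida] - dt[hit]) + dt[hit] * frac[hit]
      status[ida] <- 1L
    }
    status[a[tcur[a] >= dur_s & status[a] == 0L]] <- 3L  # timed out, in domain
  }
  minutes <- seq(output_interval_min, duration_min, by = output_interval_min)
  counts <- vapply(minutes, function(m) sum(arrival <= m * 60, na.rm = TRUE),
                   numeric(1))
  out <- data.frame(minute = minutes, count = as.integer(counts))
  attr(out, "arrival_s") <- arrival
  attr(out, "n") <- n
  attr(out, "seed") <- seed
  attr(out, "scheme") <- scheme
  attr(out, "drag") <- drag
  attr(out, "stuck") <- sum(status == 2L)
  attr(out, "flow_rate_lpm") <- field$bc$flow_rate_lpm
  attr(out, "fillet_radius") <- spec$fillet_radius
  class(out) <- c("residence_table", class(out))
  out
}
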