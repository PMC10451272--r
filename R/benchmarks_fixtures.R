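#' Analytic verification fixtures
#'
#' Each `make_*_case()` constructor returns a `fixture_case`: a
#' self-contained benchmark with the inputs needed to run one solver on a
#' small grid, a closed-form solution, and the tolerance at which the
#' numerical result is expected to match. The test suite (and
#' `fixture_check()`) runs them; nothing is downloaded or stored on disk.
#'
#' @name fixtures
NULL

new_fixture <- function(name, params, exact, tolerance, runner) {
  stopifnot(tolerance > 0)
  structure(list(name = name, params = params, exact = exact,
                 tolerance = tolerance, runner = runner),
            class = "fixture_case")
}

#' Plane Poiseuille channel fixture
#'
#' A wide straight channel (width >> gap) carrying a Newtonian fluid. The
#' exact mid-channel profile is parabolic with `max/mean = 1.5` and the
#' pressure gradient is `12 mu Q / (w gap^3)`.
#'
#' @param gap channel gap, cm.
#' @param length,width channel length and width, cm.
#' @param flow_rate_lpm flow rate, L/min.
#' @param viscosity dynamic viscosity, Pa s.
#' @param nz cells across the gap.
#' @param resolution in-plane cells per cm.
#' @return a `fixture_case`; its runner returns the solved [solve_flow()]
#'   field plus profile and pressure-gradient diagnostics.
#' @export
make_poiseuille_case <- function(gap = 0.25, length = 6, width = 10,
                                 flow_rate_lpm = 0.1, viscosity = 0.004,
                                 nz = 20, resolution = 2) {
  stopifnot(gap > 0, length > 0)
  Q <- flow_rate_lpm * 1e-3 / 60
  w_m <- width / 100; h_m <- gap / 100
  dpdx_exact <- 12 * viscosity * Q / (w_m * h_m^3)
  ubar <- Q / (w_m * h_m)
  exact <- list(
    dpdx = dpdx_exact,
    max_over_mean = 1.5,
    profile = function(z_frac) 6 * ubar * z_frac * (1 - z_frac))
  runner <- function() {
    sp <- device_spec(0, chamber_length = length, chamber_width = width,
                      chamber_height = gap, tube_inner_diameter = gap / 2,
                      port_inset = gap, plexiglass_thickness = 0.5)
    gr <- suppressWarnings(build_grid(sp, resolution = resolution,
                                      nz_blood = nz, include_shell = FALSE))
    eps <- 1e-7
    rh <- blood_rheology(mu0 = viscosity + eps, mu_inf = viscosity)
    ff <- solve_flow(gr, rh, flow_bc(flow_rate_lpm, type = "channel_x"),
                     inertia = FALSE, tol = 1e-6, max_iter = 6)
    nx <- gr$nx; ny <- gr$ny
    prof <- ff$Uc[nx %/% 2, ny %/% 2, ]
    pbar <- apply(ff$p, 1, mean)
    i1 <- max(2, nx %/% 4); i2 <- min(nx - 1, (3 * nx) %/% 4)
    dpdx <- (pbar[i1] - pbar[i2]) / ((i2 - i1) * gr$dx / 100)
    list(field = ff, profile = prof, max_over_mean = max(prof) / mean(prof),
         dpdx = dpdx)
  }
  new_fixture("poiseuille",
              list(gap = gap, length = length, width = width,
                   flow_rate_lpm = flow_rate_lpm, viscosity = viscosity,
                   nz = nz, resolution = resolution),
              exact, tolerance = 0.02, runner)
}

#' Beer-Lambert slab fixture
#'
#' Absorption-only photon transport into a slab: the transmitted fraction is
#' `exp(-mu_a L)` and the deposited power density decays as
#' `mu_a exp(-mu_a z)`.
#'
#' @param mu_a absorption coefficient, 1/cm.
#' @param thickness slab thickness, cm.
#' @param n_photons photons for the runner.
#' @param seed RNG seed.
#' @return a `fixture_case`; the runner returns the kernel plus the on-axis
#'   depth profile and the Monte Carlo standard error of the transmitted
#'   fraction.
#' @export
make_beer_lambert_case <- function(mu_a = 1.56, thickness = 1,
                                   n_photons = 1e5, seed = 7) {
  stopifnot(mu_a > 0, thickness >= 0)
  exact <- list(
    transmitted = exp(-mu_a * thickness),
    absorbed = 1 - exp(-mu_a * thickness),
    depth_density = function(z) mu_a * exp(-mu_a * z))
  runner <- function() {
    if (thickness == 0) return(list(transmitted = 1, kernel = NULL, se = 0))
    k <- run_photon_transport(optical_properties(mu_a = mu_a, mu_s = 0),
                              beam_spec(profile = "flat"),
                              n_photons = n_photons,
                              slab_thickness = thickness, seed = seed,
                              dr = 0.01, dz = 0.01)
    p <- exp(-mu_a * thickness)
    list(kernel = k, transmitted = k$totals$transmitted,
         absorbed = k$totals$absorbed,
         se = sqrt(p * (1 - p) / n_photons))
  }
  new_fixture("beer_lambert",
              list(mu_a = mu_a, thickness = thickness,
                   n_photons = n_photons, seed = seed),
              exact, tolerance = 3, runner)   # tolerance in standard errors
}

#' Heated slab fixture
#'
#' One-dimensional slab with a uniform volumetric source and symmetric Robin
#' (film) boundaries; the closed-form maximum excess temperature is
#' `q L^2 / (8 kappa) + q L / (2 h)`.
#'
#' @param q volumetric source, W/m^3.
#' @param h film coefficient, W/(m^2 K).
#' @param kappa conductivity, W/(m K).
#' @param L slab thickness, m.
#' @param nz cells through the slab.
#' @return a `fixture_case`; the runner returns the solved field and its
#'   maximum excess temperature.
#' @export
make_heated_slab_case <- function(q = 5000, h = 10, kappa = 0.55,
                                  L = 0.01, nz = 40) {
  stopifnot(q >= 0, h > 0, kappa > 0, L > 0)
  exact <- list(dT_max = q * L^2 / (8 * kappa) + q * L / (2 * h),
                dT_dirichlet = q * L^2 / (8 * kappa))
  runner <- function() {
    sp <- device_spec(0, chamber_length = 2, chamber_width = 2,
                      chamber_height = L * 100,
                      tube_inner_diameter = 0.3, port_inset = 0.5)
    gr <- suppressWarnings(build_grid(sp, resolution = 1, nz_blood = nz,
                                      include_shell = FALSE))
    src <- structure(list(q = array(q, dim(gr$mask))), class = "fluence_field")
    pr <- thermal_properties(blood_k = kappa)
    res <- solve_heat(gr, flow = NULL, source = src, props = pr,
                      bc = thermal_bc(h_fixed = h, lateral = "adiabatic"))
    list(result = res, dT_max = max(res$T_steady, na.rm = TRUE) - 20)
  }
  new_fixture("heated_slab", list(q = q, h = h, kappa = kappa, L = L, nz = nz),
              exact, tolerance = 0.01, runner)
}

#' Geometrically scaled-down device
#'
#' Shrinks the footprint (length, width, fillet, port insets, tube bore) by
#' `scale` at fixed chamber height, for desk-scale runs; reports the matched
#' dimensionless groups (tube Reynolds number, chamber Peclet number) so the
#' reduction is explicit.
#'
#' @param spec a [device_spec()].
#' @param scale footprint scale factor in (0, 1].
#' @param resolution in-plane cells per cm for the returned grid.
#' @param flow_rate_lpm reference flow rate for the dimensionless numbers.
#' @return list with the scaled `spec`, its `grid` and `dimensionless`
#'   numbers.
#' @export
make_reduced_device <- function(spec, scale = 0.5, resolution = 4,
                                flow_rate_lpm = 0.25) {
  stopifnot(scale > 0, scale <= 1)
  sp2 <- device_spec(
    fillet_radius = spec$fillet_radius * scale,
    chamber_length = spec$chamber_length * scale,
    chamber_width = spec$chamber_width * scale,
    chamber_height = spec$chamber_height,
    plexiglass_thickness = spec$plexiglass_thickness,
    tube_inner_diameter = spec$tube_inner_diameter * scale,
    tube_outer_diameter = spec$tube_outer_diameter * scale,
    tube_height = spec$tube_height,
    port_inset = spec$port_inset * scale,
    port_scaling_factor = spec$port_scaling_factor)
  gr <- suppressWarnings(build_grid(sp2, resolution = resolution,
                                    include_shell = FALSE))
  rh <- blood_rheology()
  Q <- flow_rate_lpm * 1e-3 / 60
  d <- sp2$tube_inner_diameter / 100
  v_t <- Q / (pi * (d / 2)^2)
  h_m <- sp2$chamber_height / 100
  ubar <- Q / ((sp2$chamber_width / 100) * h_m)
  mu <- carreau_viscosity(8 * v_t / d, rh)
  alpha <- 0.55 / (1057 * 3600)
  list(spec = sp2, grid = gr,
       dimensionless = c(Re_tube = 1057 * v_t * d / mu,
                         Pe_chamber = ubar * h_m / alpha))
}

#' Run a fixture and report the comparison
#'
#' @param case a `fixture_case`.
#' @return list with the runner output, the exact values and `pass`.
#' @export
fixture_check <- function(case) {
  stopifnot(inherits(case, "fixture_case"))
  out <- case$runner()
  pass <- switch(case$name,
    poiseuille = abs(out$max_over_mean - 1.5) / 1.5 < case$tolerance,
    beer_lambert = is.null(out$kernel) ||
      abs(out$transmitted - case$exact$transmitted) < case$tolerance * out$se,
    heated_slab = abs(out$dT_max - case$exact$dT_max) /
      case$exact$dT_max < case$tolerance,
    TRUE)
  list(name = case$name, output = out, exact = case$exact, pass = pass)
}
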