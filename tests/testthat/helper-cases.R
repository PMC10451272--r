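# Shared fixtures and a per-session cache so expensive solver objects are
# built once and reused across test files.

.pe_cache <- new.env(parent = emptyenv())

pe_cached <- function(name, expr) {
  if (!exists(name, envir = .pe_cache)) {
    assign(name, force(expr), envir = .pe_cache)
  }
  get(name, envir = .pe_cache)
}

# small square device (8 x 8 x 1 cm) for fast flow/thermal checks
small_device <- function(fillet = 0) {
  device_spec(fillet, chamber_length = 8, chamber_width = 8,
              chamber_height = 1, tube_inner_diameter = 0.8,
              port_inset = 1.0, port_scaling_factor = 0.3)
}

small_flow <- function(rate = 0.1, fillet = 0, resolution = 2, nz = 4,
                       inertia = TRUE) {
  key <- sprintf("smallflow_%g_%g_%g_%g_%d", rate, fillet, resolution, nz,
                 inertia)
  pe_cached(key, {
    sp <- small_device(fillet)
    gr <- suppressWarnings(build_grid(sp, resolution, nz_blood = nz,
                                      include_shell = FALSE))
    solve_flow(gr, blood_rheology(), flow_bc(rate), inertia = inertia,
               max_iter = 40)
  })
}

# a synthetic uniform vertical plug field on a tiny chamber whose inlet and
# outlet coincide at the centre: every particle crosses the 1 cm gap at the
# same speed, giving an exact closed-form arrival time
plug_field <- function(w0 = 0.01 / 150) {
  pe_cached(sprintf("plug_%g", w0), {
    sp <- device_spec(0, chamber_length = 2, chamber_width = 2,
                      chamber_height = 1, tube_inner_diameter = 0.8,
                      port_inset = 1.0)
    gr <- suppressWarnings(build_grid(sp, resolution = 4, nz_blood = 5,
                                      include_shell = FALSE))
    nx <- gr$nx; ny <- gr$ny; nz <- gr$nz
    structure(list(
      grid = gr, spec = sp, rheology = blood_rheology(),
      bc = flow_bc(0.1),
      mask2d = gr$mask[, , 1] == 1L,
      Uc = array(0, c(nx, ny, nz)), Vc = array(0, c(nx, ny, nz)),
      Wc = array(w0, c(nx, ny, nz)),
      u = array(0, c(nx + 1, ny, nz)), v = array(0, c(nx, ny + 1, nz)),
      w = array(w0, c(nx, ny, nz + 1)),
      qin_col = matrix(0, nx, ny), qout_col = matrix(0, nx, ny),
      dx_m = gr$dx / 100, dy_m = gr$dy / 100, dz_m = gr$dzc[1] / 100
    ), class = "flow_field")
  })
}

small_shell_grid <- function() {
  pe_cached("grid_small_shell",
            suppressWarnings(build_grid(small_device(), 2, nz_blood = 4)))
}

device_kernel <- function() {
  pe_cached("kernel_device",
            run_photon_transport(optical_properties(), beam_spec(), 1e5,
                                 seed = 4, dr = 0.005, dz = 0.005))
}

small_thermal <- function() {
  pe_cached("thermal_small", {
    gt <- small_shell_grid()
    ff <- small_flow(0.1)
    layout <- data.frame(x = c(3, 5, 3, 5), y = c(3, 3, 5, 5),
                         face = c("top", "top", "bottom", "bottom"))
    fl <- assemble_led_array(device_kernel(), gt, layout = layout)
    list(thermal = solve_heat(gt, flow = ff, source = fl, duration_min = 2,
                              dt_grow = 2, dt_max = 5, snapshot_min = 2),
         fluence = fl)
  })
}

# the full study sweep used by the acceptance tests (resolution 2 = 5 mm
# cells, 6 blood layers, 1e5 photons, transient only where a 5-min metric
# is asserted, tracing at the 0.25 L/min rate the criteria reference)
acceptance_bundle <- function() {
  pe_cached("acceptance_bundle", {
    cfg <- pe_config(seed = 42, trace_rates = 0.25)
    run_pipeline(cfg, transient_for = data.frame(geometry = 2, rate = 1),
                 quiet = TRUE)
  })
}

# independent rasterization of a filleted-rectangle area (oracle: corner
# circle test written from scratch, no package geometry helpers)
raster_area_oracle <- function(L, W, r, n = 400) {
  xs <- (seq_len(n) - 0.5) * (L / n)
  ys <- (seq_len(n) - 0.5) * (W / n)
  inside <- outer(xs, ys, function(x, y) {
    ok <- x >= 0 & x <= L & y >= 0 & y <= W
    corner <- function(cx, cy) (x - cx)^2 + (y - cy)^2 <= r^2
    in_corner_zone <- (x < r & y < r) | (x > L - r & y < r) |
      (x < r & y > W - r) | (x > L - r & y > W - r)
    cc <- corner(pmin(pmax(x, r), L - r), pmin(pmax(y, r), W - r))
    ok & (!in_corner_zone | cc)
  })
  mean(inside) * L * W
}
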