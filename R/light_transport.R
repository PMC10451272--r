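#' Optical properties of the blood pool
#'
#' Absorption, scattering and anisotropy used by the photon random walk.
#' The default is the fully carboxyhemoglobin-poisoned pool at 620 nm
#' (absorption 1.56 1/cm) with scattering disabled, the absorption-dominated
#' configuration whose deposition has a Beer-Lambert closed form. Literature
#' scattering values for whole blood are available from [blood_optics_620()];
#' they are deliberately not silently defaulted because the device model's
#' reference optics are absorption-only (see the methods vignette).
#'
#' @param mu_a absorption coefficient, 1/cm. At 620 nm: HbCO 1.56, HbO 1.12,
#'   Hb 6.12 (see [chromophore_mu_a()]).
#' @param mu_s scattering coefficient, 1/cm.
#' @param g scattering anisotropy (mean cosine, Henyey-Greenstein), in (-1, 1).
#' @param refractive_index pool refractive index (boundaries are treated as
#'   index-matched; no Fresnel reflection is modelled).
#' @return object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a = 1.56, mu_s = 0, g = 0,
                               refractive_index = 1.37) {
  stopifnot(mu_a >= 0, mu_s >= 0, g > -1, g < 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g,
                 refractive_index = refractive_index),
            class = "optical_properties")
}

#' Absorption coefficients of hemoglobin species at 620 nm
#'
#' @param species character vector among `"HbCO"`, `"HbO"`, `"Hb"`.
#' @return absorption coefficients, 1/cm.
#' @export
chromophore_mu_a <- function(species = "HbCO") {
  tab <- c(HbCO = 1.56, HbO = 1.12, Hb = 6.12)
  if (!all(species %in% names(tab))) stop("unknown chromophore")
  tab[species]
}

#' Literature-style whole-blood optics at 620 nm
#'
#' Strongly forward-scattering values representative of oxygenated whole
#' blood in the red (scattering ~ 650 1/cm, g ~ 0.982). `reduced = TRUE`
#' returns the similarity-transformed equivalent (`mu_s' = mu_s * (1 - g)`,
#' `g = 0`), which reproduces the same diffuse deposition at a small fraction
#' of the random-walk steps.
#'
#' @param mu_a absorption, 1/cm (default the HbCO value).
#' @param reduced apply the similarity reduction.
#' @return an [optical_properties()].
#' @export
blood_optics_620 <- function(mu_a = 1.56, reduced = FALSE) {
  mu_s <- 650; g <- 0.982
  if (reduced) optical_properties(mu_a, mu_s * (1 - g), 0)
  else optical_properties(mu_a, mu_s, g)
}

#' LED beam specification
#'
#' @param radius beam radius, cm (Gaussian 1/e^2 radius, or the hard radius
#'   of a flat beam).
#' @param power continuous optical power per LED, W. The device's stated
#'   per-LED input energy of 0.036 J is interpreted as 0.036 W of continuous
#'   power during irradiation (the steady heating model needs a power);
#'   0.035 is the alternative printed value, selectable here.
#' @param wavelength nm (reporting only).
#' @param profile `"gaussian"` or `"flat"`.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(radius = 0.33, power = 0.036, wavelength = 620,
                      profile = c("gaussian", "flat")) {
  stopifnot(radius > 0, power > 0)
  structure(list(radius = radius, power = power, wavelength = wavelength,
                 profile = match.arg(profile)), class = "beam_spec")
}

#' Monte Carlo photon transport into a blood slab
#'
#' MCML-style weighted random walk for a single normally incident LED beam:
#' launch radii sampled from the beam profile, exponential step lengths
#' `-log(xi) / (mu_a + mu_s)`, a fraction `mu_a / (mu_a + mu_s)` of the
#' photon weight deposited into the cylindrical `(r, z)` scoring grid at
#' every interaction, Henyey-Greenstein deflection, and Russian-roulette
#' termination below a weight threshold. Boundaries are index-matched:
#' photons crossing `z = 0` are scored as back-reflected, photons crossing
#' the slab bottom as transmitted. The run is deterministic given `seed`.
#'
#' The returned kernel stores the absorbed fraction per `(r, z)` bin,
#' normalized to unit input power, plus a closed weight ledger: absorbed +
#' transmitted + reflected + residual-in-flight + roulette imbalance = 1 to
#' machine precision.
#'
#' @param optics an [optical_properties()].
#' @param beam a [beam_spec()].
#' @param n_photons number of photons (>= 1; >= 1e3 recommended).
#' @param slab_thickness blood slab thickness, cm.
#' @param seed RNG seed.
#' @param dr,dz scoring bin sizes, cm.
#' @param r_extent,z_extent scoring grid extents, cm (deposition beyond them
#'   is accumulated in an out-of-grid bucket so the ledger stays closed).
#' @param w_min roulette weight threshold.
#' @param roulette_p roulette survival probability.
#' @param max_steps hard cap on random-walk steps.
#' @return object of class `deposition_kernel`.
#' @export
run_photon_transport <- function(optics, beam, n_photons = 1e5,
                                 slab_thickness = 1, seed = 1,
                                 dr = 0.001, dz = 0.001,
                                 r_extent = 1.0, z_extent = 1.5,
                                 w_min = 1e-4, roulette_p = 0.1,
                                 max_steps = 1e5) {
  if (n_photons < 1) stop("n_photons must be positive", call. = FALSE)
  mu_a <- optics$mu_a; mu_s <- optics$mu_s
  mu_t <- mu_a + mu_s
  if (mu_t <= 0)
    stop("ballistic-transit: mu_a + mu_s = 0, no interaction medium",
         call. = FALSE)
  g <- optics$g
  set.seed(seed)
  n <- as.integer(n_photons)
  nr <- as.integer(round(r_extent / dr))
  nzb <- as.integer(round(z_extent / dz))
  dep <- numeric(nr * nzb)

  # launch
  u <- stats::runif(n)
  r0 <- if (beam$profile == "gaussian") beam$radius * sqrt(-log(u) / 2)
        else beam$radius * sqrt(u)
  phi0 <- 2 * pi * stats::runif(n)
  x <- r0 * cos(phi0); y <- r0 * sin(phi0); z <- numeric(n)
  ux <- numeric(n); uy <- numeric(n); uz <- rep(1, n)
  w <- rep(1, n)   # per-photon weight; totals normalized by n at the end

  absorbed_out <- 0; transmitted <- 0; reflected <- 0; roulette_net <- 0
  albedo <- mu_a / mu_t
  step <- 0L
  while (length(w) > 0 && step < max_steps) {
    step <- step + 1L
    s <- -log(stats::runif(length(w))) / mu_t
    x <- x + ux * s; y <- y + uy * s; z <- z + uz * s
    out_top <- z < 0
    out_bot <- z > slab_thickness
    if (any(out_top)) reflected <- reflected + sum(w[out_top])
    if (any(out_bot)) transmitted <- transmitted + sum(w[out_bot])
    keep <- !(out_top | out_bot)
    if (!all(keep)) {
      x <- x[keep]; y <- y[keep]; z <- z[keep]
      ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]; w <- w[keep]
    }
    if (length(w) == 0) break
    # deposit
    dw <- w * albedo
    r <- sqrt(x^2 + y^2)
    ir <- floor(r / dr) + 1
    iz <- floor(z / dz) + 1
    ingrid <- ir <= nr & iz <= nzb
    if (any(!ingrid)) absorbed_out <- absorbed_out + sum(dw[!ingrid])
    if (any(ingrid)) {
      idx <- (iz[ingrid] - 1L) * nr + ir[ingrid]
      acc <- rowsum(dw[ingrid], idx)
      dep[as.integer(rownames(acc))] <- dep[as.integer(rownames(acc))] + acc[, 1]
    }
    w <- w - dw
    if (mu_s == 0) { # nothing survives an interaction: pure absorption
      w <- numeric(0)
      break
    }
    # Henyey-Greenstein deflection
    m <- length(w)
    xi <- stats::runif(m)
    ct <- if (abs(g) < 1e-8) 2 * xi - 1 else {
      tmp <- (1 - g^2) / (1 - g + 2 * g * xi)
      (1 + g^2 - tmp^2) / (2 * g)
    }
    ct <- pmin(1, pmax(-1, ct))
    st <- sqrt(1 - ct^2)
    phi <- 2 * pi * stats::runif(m)
    cp <- cos(phi); sp <- sin(phi)
    near_pole <- abs(uz) > 0.99999
    den <- sqrt(pmax(1 - uz^2, 1e-30))
    nux <- ifelse(near_pole, st * cp,
                  st * (ux * uz * cp - uy * sp) / den + ux * ct)
    nuy <- ifelse(near_pole, st * sp,
                  st * (uy * uz * cp + ux * sp) / den + uy * ct)
    nuz <- ifelse(near_pole, sign(uz) * ct, -den * st * cp + uz * ct)
    nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
    ux <- nux / nrm; uy <- nuy / nrm; uz <- nuz / nrm
    # roulette
    low <- w < w_min
    if (any(low)) {
      surv <- stats::runif(sum(low)) < roulette_p
      wl <- w[low]
      roulette_net <- roulette_net + sum(wl[!surv])           # weight removed
      roulette_net <- roulette_net - sum(wl[surv] * (1 / roulette_p - 1))
      wl[surv] <- wl[surv] / roulette_p
      wl[!surv] <- NA
      w[low] <- wl
      keep <- !is.na(w)
      x <- x[keep]; y <- y[keep]; z <- z[keep]
      ux <- ux[keep]; uy <- uy[keep]; uz <- uz[keep]; w <- w[keep]
    }
  }
  residual <- sum(w) / n
  dep <- matrix(dep, nr, nzb) / n
  absorbed_out <- absorbed_out / n
  transmitted <- transmitted / n
  reflected <- reflected / n
  roulette_net <- roulette_net / n
  structure(list(
    dep = dep, dr = dr, dz = dz, nr = nr, nz = nzb,
    r_edges = seq(0, r_extent, by = dr), z_edges = seq(0, z_extent, by = dz),
    slab_thickness = slab_thickness,
    totals = list(absorbed = sum(dep) + absorbed_out,
                  absorbed_in_grid = sum(dep),
                  absorbed_out_of_grid = absorbed_out,
                  transmitted = transmitted, reflected = reflected,
                  residual = residual, roulette_net = roulette_net),
    params = list(optics = optics, beam = beam, n_photons = n,
                  seed = seed, steps = step)
  ), class = "deposition_kernel")
}

#' Absorbed power density lookup from a deposition kernel
#'
#' Piecewise-constant volumetric density (W/cm^3 per W of beam power) of the
#' cylindrically symmetric kernel at radius `r` and depth `z`.
#'
#' @param kernel a [run_photon_transport()] result.
#' @param r,z radius and depth, cm (vectorized).
#' @return density values, W/cm^3 per W input.
#' @export
kernel_density <- function(kernel, r, z) {
  ir <- floor(r / kernel$dr) + 1
  iz <- floor(z / kernel$dz) + 1
  ok <- ir >= 1 & ir <= kernel$nr & iz >= 1 & iz <= kernel$nz & z >= 0
  out <- numeric(length(r))
  if (any(ok)) {
    r1 <- (ir[ok] - 1) * kernel$dr
    r2 <- ir[ok] * kernel$dr
    shell_vol <- pi * (r2^2 - r1^2) * kernel$dz
    out[ok] <- kernel$dep[cbind(ir[ok], iz[ok])] / shell_vol
  }
  out
}

#' Revolve a 2D deposition kernel into a 3D per-LED source
#'
#' Produces the volumetric absorbed-power density of one LED on a local
#' Cartesian grid by revolving the cylindrical `(r, z)` kernel 360 degrees.
#' Cell values are subcell-averaged so that the volume integral conserves the
#' kernel's absorbed fraction (times the beam power) to within a fraction of
#' a percent.
#'
#' @param kernel a [run_photon_transport()] result (unit input power).
#' @param dx,dz_out output cell sizes, cm.
#' @param nsub subsamples per axis per cell for averaging.
#' @param power beam power to scale by, W (default 1, i.e. a unit kernel).
#' @return object of class `led_source`: 3D array `q` (W/cm^3) on a local
#'   grid centred on the beam axis with `z` the depth into the blood.
#' @export
revolve_kernel <- function(kernel, dx = 0.05, dz_out = 0.05, nsub = 3,
                           power = 1) {
  if (any(!is.finite(kernel$dep)) || any(kernel$dep < 0))
    stop("kernel contains NaN or negative cells", call. = FALSE)
  re <- kernel$nr * kernel$dr
  zmax <- min(kernel$slab_thickness, kernel$nz * kernel$dz)
  nxl <- 2L * as.integer(ceiling(re / dx))
  nzl <- as.integer(ceiling(zmax / dz_out))
  xc <- (seq_len(nxl) - 0.5) * dx - re
  zc <- (seq_len(nzl) - 0.5) * dz_out
  off <- (seq_len(nsub) - (nsub + 1) / 2) / nsub
  q <- array(0, c(nxl, nxl, nzl))
  for (k in seq_len(nzl)) {
    acc <- matrix(0, nxl, nxl)
    for (oz in off) {
      zs <- zc[k] + oz * dz_out
      for (oxi in off) for (oyi in off) {
        gx <- matrix(xc + oxi * dx, nxl, nxl)
        gy <- matrix(xc + oyi * dx, nxl, nxl, byrow = TRUE)
        rr <- sqrt(gx^2 + gy^2)
        acc <- acc + kernel_density(kernel, as.vector(rr), rep(zs, nxl * nxl))
      }
    }
    q[, , k] <- acc / (nsub^3)
  }
  q <- q * power
  structure(list(q = q, xc = xc, yc = xc, zc = zc, dx = dx, dz = dz_out,
                 power = power,
                 total = sum(q) * dx * dx * dz_out,
                 absorbed_fraction = kernel$totals$absorbed),
            class = "led_source")
}

#' Default LED array layout
#'
#' Twenty LEDs per face arranged as a 4 x 5 grid at 5 cm pitch centred on the
#' chamber face (the 5-position axis spans the full 20 cm face, so its end
#' rows lie on the face edges). Both faces use the same in-plane positions.
#'
#' @param spec a [device_spec()].
#' @param pitch LED spacing, cm.
#' @param n_x,n_y LEDs along x and y.
#' @param faces character subset of `c("top", "bottom")`.
#' @return data.frame with columns `x`, `y`, `face`.
#' @export
led_layout <- function(spec, pitch = 5, n_x = 4, n_y = 5,
                       faces = c("top", "bottom")) {
  cx <- spec$chamber_length / 2; cy <- spec$chamber_width / 2
  xs <- cx + (seq_len(n_x) - (n_x + 1) / 2) * pitch
  ys <- cy + (seq_len(n_y) - (n_y + 1) / 2) * pitch
  g <- expand.grid(x = xs, y = ys)
  out <- do.call(rbind, lapply(faces, function(f) cbind(g, face = f)))
  out$face <- as.character(out$face)
  out
}

#' Superpose the LED array into a volumetric heat source
#'
#' Places one deposition kernel at every LED position (top sources depositing
#' downward from the top blood face, bottom sources upward from the bottom
#' face), scales each by the plexiglass transmission, and accumulates the
#' absorbed power density onto the blood cells of a structured grid. Sources
#' whose centre falls outside the filleted footprint are excluded with a
#' warning; deposition falling laterally outside the blood mask is clipped
#' and reported in the power ledger.
#'
#' @param kernel a unit-power [run_photon_transport()] result.
#' @param grid a [build_grid()] result.
#' @param spec the [device_spec()] (defaults to the grid's).
#' @param layout LED positions from [led_layout()] (or any data.frame with
#'   `x`, `y`, `face`).
#' @param beam the [beam_spec()] giving per-LED power.
#' @param transmission scalar plexiglass transmission factor in (0, 1].
#' @param nsub in-plane subsamples per cell when averaging the kernel.
#' @return object of class `fluence_field`: array `q` of absorbed power
#'   density (W/m^3) on the grid, per-LED power ledger, and totals.
#' @export
assemble_led_array <- function(kernel, grid, spec = grid$spec,
                               layout = led_layout(spec),
                               beam = kernel$params$beam,
                               transmission = 0.92, nsub = 3) {
  stopifnot(transmission > 0, transmission <= 1)
  h <- spec$chamber_height
  kz <- grid$kz_blood
  q <- array(0, dim(grid$mask))          # W/cm^3, blood layers only
  dxg <- grid$dx
  off <- (seq_len(nsub) - (nsub + 1) / 2) / nsub * dxg
  re <- kernel$nr * kernel$dr
  abs_frac <- kernel$totals$absorbed
  Pled <- beam$power * transmission
  ledger <- layout
  ledger$delivered <- Pled
  ledger$absorbed_in_blood <- 0
  ledger$clipped <- 0
  ledger$excluded <- FALSE
  nzsub <- 3
  for (s in seq_len(nrow(layout))) {
    x0 <- layout$x[s]; y0 <- layout$y[s]; face <- layout$face[s]
    if (footprint_sdf(spec, x0, y0) > 0) {
      warning("LED source centre (", x0, ", ", y0,
              ") lies outside the footprint; excluded")
      ledger$excluded[s] <- TRUE
      ledger$delivered[s] <- 0
      next
    }
    ii <- which(abs(grid$xc - x0) < re + dxg)
    jj <- which(abs(grid$yc - y0) < re + dxg)
    if (!length(ii) || !length(jj)) next
    cols <- expand.grid(i = ii, j = jj)
    # subsampled in-plane radii for every candidate column
    rsub <- matrix(0, nrow(cols), nsub * nsub)
    m <- 1
    for (oxi in off) for (oyi in off) {
      rsub[, m] <- sqrt((grid$xc[cols$i] + oxi - x0)^2 +
                        (grid$yc[cols$j] + oyi - y0)^2)
      m <- m + 1
    }
    s_all <- 0; s_in <- 0
    contrib <- vector("list", length(kz))
    for (ki in seq_along(kz)) {
      k <- kz[ki]
      zc <- grid$zc[k]; dzk <- grid$dzc[k]
      zoff <- (seq_len(nzsub) - (nzsub + 1) / 2) / nzsub * dzk
      depth0 <- if (face == "top") h - zc else zc
      dens <- numeric(nrow(cols))
      for (zo in zoff) {
        d <- depth0 + if (face == "top") -zo else zo
        for (m in seq_len(nsub * nsub))
          dens <- dens + kernel_density(kernel, rsub[, m], rep(d, nrow(cols)))
      }
      dens <- dens / (nsub * nsub * nzsub)
      vol <- dxg * grid$dy * dzk
      inmask <- grid$mask[cbind(cols$i, cols$j, k)] == 1L
      s_all <- s_all + sum(dens) * vol
      s_in <- s_in + sum(dens[inmask]) * vol
      contrib[[ki]] <- list(k = k, dens = dens, inmask = inmask)
    }
    if (s_all <= 0) next
    scale <- abs_frac * Pled / s_all
    for (ci in contrib) {
      idx <- cbind(cols$i[ci$inmask], cols$j[ci$inmask], ci$k)
      q[idx] <- q[idx] + ci$dens[ci$inmask] * scale
    }
    ledger$absorbed_in_blood[s] <- s_in * scale
    ledger$clipped[s] <- abs_frac * Pled - s_in * scale
  }
  structure(list(
    q = q * 1e6,                        # W/m^3
    q_Wcm3 = q,
    grid = grid, layout = layout, ledger = ledger,
    transmission = transmission,
    totals = list(
      delivered = sum(ledger$delivered),
      absorbed_in_blood = sum(ledger$absorbed_in_blood),
      clipped = sum(ledger$clipped),
      n_sources = nrow(layout), n_excluded = sum(ledger$excluded))
  ), class = "fluence_field")
}

#' Total absorbed optical power of a fluence field
#'
#' Volume integral of the absorbed power density over blood cells, W.
#'
#' @param field a [assemble_led_array()] result.
#' @return watts.
#' @export
absorbed_power <- function(field) {
  g <- field$grid
  tot <- 0
  for (k in seq_len(g$nz)) {
    tot <- tot + sum(field$q_Wcm3[, , k][g$mask[, , k] == 1L]) *
      g$dx * g$dy * g$dzc[k]
  }
  tot
}

#' Save / load a deposition kernel as plain text
#'
#' The kernel matrix is written as TSV and the axes, totals and parameters as
#' an accompanying JSON file (`<path>.meta.json`).
#'
#' @param kernel a [run_photon_transport()] result.
#' @param path TSV path.
#' @export
write_kernel <- function(kernel, path) {
  utils::write.table(kernel$dep, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(dr = kernel$dr, dz = kernel$dz, nr = kernel$nr, nz = kernel$nz,
               slab_thickness = kernel$slab_thickness,
               totals = kernel$totals,
               n_photons = kernel$params$n_photons,
               seed = kernel$params$seed,
               mu_a = kernel$params$optics$mu_a,
               mu_s = kernel$params$optics$mu_s,
               g = kernel$params$optics$g,
               beam = unclass(kernel$params$beam))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
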