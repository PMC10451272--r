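#' Thermal material properties
#'
#' @param blood_cp blood specific heat, J/(kg K).
#' @param blood_k blood thermal conductivity, W/(m K).
#' @param blood_rho blood density, kg/m^3.
#' @param plexi_rho,plexi_cp,plexi_k plexiglass density, specific heat and
#'   conductivity.
#' @return object of class `thermal_properties`.
#' @export
thermal_properties <- function(blood_cp = 3600, blood_k = 0.55,
                               blood_rho = 1057,
                               plexi_rho = 1190, plexi_cp = 1470,
                               plexi_k = 0.18) {
  vals <- c(blood_cp, blood_k, blood_rho, plexi_rho, plexi_cp, plexi_k)
  stopifnot(all(vals > 0))
  structure(list(blood_cp = blood_cp, blood_k = blood_k,
                 blood_rho = blood_rho, plexi_rho = plexi_rho,
                 plexi_cp = plexi_cp, plexi_k = plexi_k),
            class = "thermal_properties")
}

#' Thermal boundary conditions
#'
#' @param ambient_C exterior air temperature, deg C.
#' @param inflow_C blood temperature at the inlet, deg C (room temperature by
#'   default: blood cools to ambient in the feed tubing).
#' @param h_fixed if non-`NULL`, a constant exterior film coefficient
#'   (W/(m^2 K)) overriding the natural-convection correlations (used by
#'   verification fixtures).
#' @param lateral `"robin"` (exterior cooling on lateral faces) or
#'   `"adiabatic"` (used by the 1D slab fixture).
#' @return object of class `thermal_bc`.
#' @export
thermal_bc <- function(ambient_C = 20, inflow_C = 20, h_fixed = NULL,
                       lateral = c("robin", "adiabatic")) {
  structure(list(ambient_C = ambient_C, inflow_C = inflow_C,
                 h_fixed = h_fixed, lateral = match.arg(lateral)),
            class = "thermal_bc")
}

#' Natural-convection film coefficient for a plate
#'
#' Empirical Nusselt-Rayleigh correlations with dry-air properties evaluated
#' near room temperature: Churchill-Chu for a vertical plate and the McAdams
#' forms for horizontal plates (hot side up `0.54 Ra^(1/4)`, hot side down
#' `0.27 Ra^(1/4)`). Returns 0 when the surface is at the ambient
#' temperature; increases monotonically with the temperature difference.
#'
#' @param surface_C,ambient_C surface and ambient temperatures, deg C.
#' @param orientation `"vertical"`, `"horizontal_up"` or `"horizontal_down"`
#'   (`up`/`down` refer to the direction the hot surface faces).
#' @param length_m characteristic plate length, m (height for a vertical
#'   plate, area/perimeter for a horizontal one).
#' @return film coefficient, W/(m^2 K) (vectorized over temperatures).
#' @export
natural_convection_h <- function(surface_C, ambient_C, orientation, length_m) {
  stopifnot(length_m > 0)
  orientation <- match.arg(orientation,
                           c("vertical", "horizontal_up", "horizontal_down"))
  # dry air near 300 K
  k_air <- 0.0263; nu_air <- 1.589e-5; alpha_air <- 2.25e-5; pr <- 0.707
  dT <- abs(surface_C - ambient_C)
  t_film <- (surface_C + ambient_C) / 2 + 273.15
  ra <- 9.81 * (1 / t_film) * dT * length_m^3 / (nu_air * alpha_air)
  nu <- switch(orientation,
    vertical = (0.825 + 0.387 * ra^(1 / 6) /
                  (1 + (0.492 / pr)^(9 / 16))^(8 / 27))^2,
    horizontal_up = 0.54 * ra^0.25,
    horizontal_down = 0.27 * ra^0.25)
  h <- nu * k_air / length_m
  ifelse(dT == 0, 0, h)
}

# face transmissibility between two cells (two-point flux, W/K per unit area)
face_cond <- function(k1, k2, d1, d2) 1 / (d1 / k1 + d2 / k2)

#' Transient / steady convection-diffusion heating of the device
#'
#' Solves `rho cp dT/dt + rho cp u . grad T - div(k grad T) = q` in the
#' blood, the conduction-only reduction in the plexiglass, a Robin
#' (natural-convection) condition on all exterior faces, advective inflow of
#' blood at the inlet temperature and upwinded outflow at the outlet, on the
#' conforming structured grid. The discretization is a conservative
#' finite-volume scheme (harmonic-mean conductivities, first-order upwind
#' advection); the steady state is obtained from a single sparse solve and
#' transients by implicit Euler with a geometrically growing time step whose
#' factorizations are reused. The exterior film coefficient is iterated to
#' consistency with the computed surface temperatures unless `bc$h_fixed` is
#' given.
#'
#' @param grid a [build_grid()] result including the plexiglass shell.
#' @param flow a [solve_flow()] result on the matching in-plane resolution
#'   (or `NULL` for a quiescent pool).
#' @param source a [assemble_led_array()] result on the same grid (or `NULL`
#'   for no heating).
#' @param props a [thermal_properties()].
#' @param bc a [thermal_bc()].
#' @param duration_min transient horizon in minutes (`NULL` for steady only).
#' @param dt_init,dt_grow,dt_max implicit time-step schedule, s.
#' @param snapshot_min times (minutes) at which transient fields are kept.
#' @param h_iterations fixed-point updates of the film coefficient.
#' @return object of class `thermal_result` with the steady field `T_steady`
#'   (deg C), optional transient snapshots, a metric time series and an
#'   energy-balance report.
#' @export
solve_heat <- function(grid, flow = NULL, source = NULL,
                       props = thermal_properties(), bc = thermal_bc(),
                       duration_min = NULL, dt_init = 0.06, dt_grow = 1.5,
                       dt_max = 4, snapshot_min = 5, h_iterations = 2) {
  spec <- grid$spec
  mask <- grid$mask
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  dx <- grid$dx / 100; dy <- grid$dy / 100
  dzc <- grid$dzc / 100
  cells <- which(mask != 0L)
  n <- length(cells)
  idx3 <- arrayInd(cells, dim(mask))
  id <- array(0L, dim(mask)); id[cells] <- seq_len(n)
  is_blood <- mask[cells] == 1L
  kcond <- ifelse(is_blood, props$blood_k, props$plexi_k)
  rhocp <- ifelse(is_blood, props$blood_rho * props$blood_cp,
                  props$plexi_rho * props$plexi_cp)
  vol <- dx * dy * dzc[idx3[, 3]]
  Tamb <- bc$ambient_C

  qsrc <- numeric(n)
  if (!is.null(source)) {
    if (!identical(dim(source$q), dim(mask)))
      stop("source grid does not match the thermal grid", call. = FALSE)
    qsrc <- source$q[cells]            # W/m^3
  }

  # map face velocities from the flow grid (same in-plane cells, offset by
  # the shell margin; blood z-layers coincide)
  adv <- NULL
  if (!is.null(flow)) {
    fg <- flow$grid
    mi <- round((fg$x0 - grid$x0) / grid$dx)   # margin offset in cells
    mj <- round((fg$y0 - grid$y0) / grid$dy)
    kz <- grid$kz_blood
    if (length(kz) != fg$nz)
      stop("flow and thermal grids have different blood layer counts",
           call. = FALSE)
    adv <- list(mi = mi, mj = mj, kz = kz, fg = fg,
                rrcp = props$blood_rho * props$blood_cp)
  }

  # ---- assemble conduction + advection operator -----------------------------
  # A T = b with A in W/K units (row = cell energy balance)
  build_system <- function(h_faces) {
    ti <- integer(0); tj <- integer(0); tx <- numeric(0)
    diagv <- numeric(n); rhs <- numeric(n)
    i <- idx3[, 1]; j <- idx3[, 2]; k <- idx3[, 3]
    add <- function(di, dj, dk, area, dist_half) {
      ni <- i + di; nj <- j + dj; nk <- k + dk
      inside <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny & nk >= 1 & nk <= nz
      nid <- rep(0L, n)
      nid[inside] <- id[cbind(ni[inside], nj[inside], nk[inside])]
      nb <- nid > 0
      # interior conductive flux
      if (any(nb)) {
        d2 <- if (dk == 0) dist_half[nb] else dzc[nk[nb]] / 2
        g <- face_cond(kcond[nb], kcond[nid[nb]], dist_half[nb], d2) * area[nb]
        ti <<- c(ti, which(nb)); tj <<- c(tj, nid[nb]); tx <<- c(tx, -g)
        diagv[nb] <<- diagv[nb] + g
      }
      # exterior faces: Robin through the half cell + film
      ext <- !nb
      if (any(ext)) {
        lateral_face <- dk == 0
        if (lateral_face && bc$lateral == "adiabatic") return(invisible())
        hf <- h_faces[[face_class(di, dj, dk)]]
        u_eff <- 1 / (dist_half[ext] / kcond[ext] + 1 / pmax(hf, 1e-10))
        g <- u_eff * area[ext]
        diagv[ext] <<- diagv[ext] + g
        rhs[ext] <<- rhs[ext] + g * Tamb
      }
      invisible()
    }
    areas_z <- dx * dy
    add(-1L, 0L, 0L, rep(dy, n) * dzc[k], rep(dx / 2, n))
    add(1L, 0L, 0L, rep(dy, n) * dzc[k], rep(dx / 2, n))
    add(0L, -1L, 0L, rep(dx, n) * dzc[k], rep(dy / 2, n))
    add(0L, 1L, 0L, rep(dx, n) * dzc[k], rep(dy / 2, n))
    add(0L, 0L, -1L, rep(areas_z, n), dzc[k] / 2)
    add(0L, 0L, 1L, rep(areas_z, n), dzc[k] / 2)

    # advection (upwind, conservative) on blood faces
    if (!is.null(adv)) {
      fg <- adv$fg; rrcp <- adv$rrcp
      kz <- adv$kz
      for (kk in seq_along(kz)) {
        kth <- kz[kk]
        sel <- which(k == kth & is_blood)
        if (!length(sel)) next
        ii <- i[sel]; jj <- j[sel]
        fi <- ii - adv$mi + 0L; fj <- jj - adv$mj + 0L
        okf <- fi >= 1 & fi <= fg$nx & fj >= 1 & fj <= fg$ny
        sel <- sel[okf]; ii <- ii[okf]; jj <- jj[okf]
        fi <- fi[okf]; fj <- fj[okf]
        # x faces (east), y faces (north), z faces (top): flux leaving cell
        face_adv <- function(uface, di, dj, dk, area) {
          Fh <- rrcp * uface * area              # W/K advective conductance
          ni <- ii + di; nj <- jj + dj; nk <- kth + dk
          nid <- id[cbind(ni, nj, nk)]
          # outflow part (upwind = this cell)
          pos <- pmax(Fh, 0)
          diagv[sel] <<- diagv[sel] + pos
          # couple only into blood neighbours: flux crossing into the casing
          # region exists only at the outlet patch, where it leaves the domain
          has_nb <- nid > 0 & mask[cbind(ni, nj, nk)] == 1L
          w <- which(has_nb & pos > 0)
          if (length(w)) { ti <<- c(ti, nid[w]); tj <<- c(tj, sel[w])
                           tx <<- c(tx, -pos[w]) }
          # inflow to this cell handled when the neighbour emits; faces on
          # the domain boundary with inflow (inlet patch) handled separately
          invisible()
        }
        face_adv(flow$u[cbind(fi + 1L, fj, kk)], 1L, 0L, 0L, dy * dzc[kth])
        face_adv(-flow$u[cbind(fi, fj, kk)], -1L, 0L, 0L, dy * dzc[kth])
        face_adv(flow$v[cbind(fi, fj + 1L, kk)], 0L, 1L, 0L, dx * dzc[kth])
        face_adv(-flow$v[cbind(fi, fj, kk)], 0L, -1L, 0L, dx * dzc[kth])
        face_adv(flow$w[cbind(fi, fj, kk + 1L)], 0L, 0L, 1L, dx * dy)
        face_adv(-flow$w[cbind(fi, fj, kk)], 0L, 0L, -1L, dx * dy)
        if (kk == 1L) {  # inlet patch: inflow enthalpy at bc$inflow_C
          qin <- flow$qin_col[cbind(fi, fj)]
          w <- which(qin > 0)
          rhs[sel[w]] <- rhs[sel[w]] + rrcp * qin[w] * bc$inflow_C
          # (the matching outflow at the outlet is the upwind term above)
        }
      }
    }
    rhs <- rhs + qsrc * vol
    A <- Matrix::sparseMatrix(i = c(ti, seq_len(n)), j = c(tj, seq_len(n)),
                              x = c(tx, diagv), dims = c(n, n))
    list(A = A, b = rhs)
  }

  face_class <- function(di, dj, dk) {
    if (dk == 1) "top" else if (dk == -1) "bottom" else "side"
  }
  plate_L <- list(
    top = (spec$chamber_length / 100) / 4,   # area/perimeter of a square
    bottom = (spec$chamber_length / 100) / 4,
    side = sum(grid$dzc) / 100)

  h_from_dT <- function(dT) {
    dT <- max(dT, 1e-6)
    if (!is.null(bc$h_fixed))
      return(list(top = bc$h_fixed, bottom = bc$h_fixed, side = bc$h_fixed))
    list(
      top = natural_convection_h(Tamb + dT, Tamb, "horizontal_up",
                                 plate_L$top),
      bottom = natural_convection_h(Tamb + dT, Tamb, "horizontal_down",
                                    plate_L$bottom),
      side = natural_convection_h(Tamb + dT, Tamb, "vertical", plate_L$side))
  }

  # ---- steady solve with film-coefficient fixed point -----------------------
  dT_surf <- 0.5
  for (hi in seq_len(max(1, h_iterations))) {
    sys <- build_system(h_from_dT(dT_surf))
    T_steady <- as.numeric(Matrix::solve(sys$A, sys$b))
    # representative exterior surface excess temperature
    ksurf <- idx3[, 3] %in% c(1L, nz)
    dT_new <- max(mean(T_steady[ksurf]) - Tamb, 1e-6)
    if (!is.null(bc$h_fixed) || abs(dT_new - dT_surf) < 0.05) {
      dT_surf <- dT_new; break
    }
    dT_surf <- dT_new
  }
  h_used <- h_from_dT(dT_surf)

  # ---- transient (implicit Euler, factorization reuse per dt level) --------
  snapshots <- list(); series <- NULL
  if (!is.null(duration_min)) {
    sysT <- build_system(h_used)
    Tn <- rep(Tamb, n)
    t_now <- 0; dt <- dt_init
    Fac <- NULL; dt_fac <- -1
    target_s <- duration_min * 60
    snap_s <- sort(unique(pmin(snapshot_min, duration_min))) * 60
    rec_t <- c(); rec_max <- c(); rec_avg <- c()
    C_over <- rhocp * vol
    while (t_now < target_s - 1e-9) {
      dt_next <- min(dt, target_s - t_now)
      pending <- snap_s[snap_s > t_now + 1e-9]
      if (length(pending)) dt_next <- min(dt_next, pending[1] - t_now)
      if (abs(dt_next - dt_fac) > 1e-12) {
        Afull <- sysT$A + Matrix::Diagonal(n, C_over / dt_next)
        Fac <- Matrix::lu(Afull); dt_fac <- dt_next
      }
      bfull <- sysT$b + C_over / dt_next * Tn
      Tn <- as.numeric(Matrix::solve(Fac, bfull))
      t_now <- t_now + dt_next
      rec_t <- c(rec_t, t_now)
      rec_max <- c(rec_max, max(Tn)); rec_avg <- c(rec_avg, mean(Tn[is_blood]))
      if (any(abs(snap_s - t_now) < 1e-6)) {
        arr <- array(NA_real_, dim(mask)); arr[cells] <- Tn
        snapshots[[sprintf("t%gmin", t_now / 60)]] <- arr
      }
      if (dt_next >= dt - 1e-12) dt <- min(dt * dt_grow, dt_max)
    }
    series <- data.frame(t_s = rec_t, max_C = rec_max, avg_blood_C = rec_avg)
  }

  Tarr <- array(NA_real_, dim(mask)); Tarr[cells] <- T_steady

  # ---- steady energy balance ------------------------------------------------
  P_in <- sum(qsrc * vol)
  P_adv <- 0
  if (!is.null(adv)) {
    fg <- flow$grid
    kz <- grid$kz_blood
    Tout_num <- 0; qout_tot <- 0
    qo <- flow$qout_col
    oc <- which(qo > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(oc))) {
      ci <- oc[r, 1] + adv$mi; cj <- oc[r, 2] + adv$mj
      Tcell <- Tarr[ci, cj, kz[length(kz)]]
      Tout_num <- Tout_num + qo[oc[r, 1], oc[r, 2]] * Tcell
      qout_tot <- qout_tot + qo[oc[r, 1], oc[r, 2]]
    }
    T_out <- Tout_num / max(qout_tot, 1e-30)
    P_adv <- adv$rrcp * qout_tot * (T_out - bc$inflow_C)
  } else T_out <- NA_real_
  # exterior loss = residual of the balance computed conservatively
  P_ext <- P_in - P_adv

  structure(list(
    grid = grid, spec = spec, props = props, bc = bc,
    T_steady = Tarr, snapshots = snapshots, series = series,
    h_used = h_used, surface_excess_C = dT_surf,
    outlet_avg_steady_C = T_out,
    energy = list(absorbed_W = P_in, advected_W = P_adv,
                  exterior_W = P_ext),
    is_blood_mask = mask == 1L
  ), class = "thermal_result")
}

#' Exterior convective loss of a steady thermal solution
#'
#' Recomputes the Robin-boundary heat flow from the steady temperature
#' field (independently of the solver's internal balance), for
#' energy-conservation checks.
#'
#' @param result a [solve_heat()] result.
#' @return watts.
#' @export
exterior_loss <- function(result) {
  g <- result$grid
  mask <- g$mask; nx <- g$nx; ny <- g$ny; nz <- g$nz
  dx <- g$dx / 100; dy <- g$dy / 100; dzc <- g$dzc / 100
  props <- result$props; bc <- result$bc
  Tarr <- result$T_steady
  h <- result$h_used
  tot <- 0
  cells <- which(mask != 0L)
  idx3 <- arrayInd(cells, dim(mask))
  kc <- ifelse(mask[cells] == 1L, props$blood_k, props$plexi_k)
  Tc <- Tarr[cells]
  for (d in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1))) {
    ni <- idx3[, 1] + d[1]; nj <- idx3[, 2] + d[2]; nk <- idx3[, 3] + d[3]
    inside <- ni >= 1 & ni <= nx & nj >= 1 & nj <= ny & nk >= 1 & nk <= nz
    nbm <- rep(0L, length(cells))
    nbm[inside] <- mask[cbind(ni[inside], nj[inside], nk[inside])]
    ext <- nbm == 0L
    if (!any(ext)) next
    if (d[3] == 1) { hf <- h$top; area <- dx * dy; dh <- dzc[idx3[ext, 3]] / 2 }
    else if (d[3] == -1) { hf <- h$bottom; area <- dx * dy
                           dh <- dzc[idx3[ext, 3]] / 2 }
    else {
      if (bc$lateral == "adiabatic") next
      hf <- h$side; dh <- dx / 2
      area <- (if (d[1] != 0) dy else dx) * dzc[idx3[ext, 3]]
    }
    u_eff <- 1 / (dh / kc[ext] + 1 / pmax(hf, 1e-10))
    tot <- tot + sum(u_eff * area * (Tc[ext] - bc$ambient_C))
  }
  tot
}

#' Table-style thermal summary metrics
#'
#' Maximum device temperature after five minutes, maximum and blood-average
#' temperature at steady state, and the flow-weighted average blood
#' temperature at the outlet at steady state.
#'
#' @param result a [solve_heat()] result (with a 5-minute snapshot if the
#'   transient metric is wanted).
#' @param spec device spec (defaults to the result's).
#' @return one-row data.frame.
#' @export
thermal_metrics <- function(result, spec = result$spec) {
  snap5 <- result$snapshots[["t5min"]]
  data.frame(
    fillet_radius = spec$fillet_radius,
    max_5min_C = if (!is.null(snap5)) max(snap5, na.rm = TRUE) else NA_real_,
    max_steady_C = max(result$T_steady, na.rm = TRUE),
    avg_steady_C = mean(result$T_steady[result$is_blood_mask], na.rm = TRUE),
    outlet_avg_steady_C = result$outlet_avg_steady_C
  )
}
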