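#' Flow boundary conditions
#'
#' @param flow_rate_lpm inlet volumetric flow rate, L/min.
#' @param outlet_pressure outlet gauge pressure, Pa (atmospheric = 0).
#' @param type `"ports"` (inlet disc on the bottom face, outlet disc on the
#'   top face, the device configuration) or `"channel_x"` (plug inflow across
#'   the x = 0 boundary and plug outflow at x = L; used by the plane-channel
#'   verification fixture).
#' @return object of class `flow_bc`.
#' @export
flow_bc <- function(flow_rate_lpm, outlet_pressure = 0,
                    type = c("ports", "channel_x")) {
  stopifnot(flow_rate_lpm > 0)
  structure(list(flow_rate_lpm = flow_rate_lpm, Q = flow_rate_lpm * 1e-3 / 60,
                 outlet_pressure = outlet_pressure, type = match.arg(type)),
            class = "flow_bc")
}

# BiCGSTAB for an implicitly defined linear operator (used for the pressure
# Schur complement; the operator is close to symmetric so convergence is fast)
bicgstab <- function(op, b, x0 = NULL, tol = 1e-9, maxit = 500) {
  n <- length(b)
  x <- if (is.null(x0) || length(x0) != n) numeric(n) else x0
  r <- b - op(x)
  bnrm <- sqrt(sum(b^2))
  if (bnrm == 0) return(numeric(n))
  if (sqrt(sum(r^2)) / bnrm < tol) return(x)
  r0 <- r
  rho <- 1; alpha <- 1; omega <- 1
  vv <- numeric(n); p <- numeric(n)
  for (i in seq_len(maxit)) {
    rho1 <- sum(r0 * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    p <- r + beta * (p - omega * vv)
    vv <- op(p)
    alpha <- rho1 / sum(r0 * vv)
    s <- r - alpha * vv
    if (sqrt(sum(s^2)) / bnrm < tol) { x <- x + alpha * p; return(x) }
    t <- op(s)
    omega <- sum(t * s) / sum(t * t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    rho <- rho1
    if (sqrt(sum(r^2)) / bnrm < tol) return(x)
  }
  warning("bicgstab: tolerance not reached in ", maxit, " iterations ",
          "(residual ", signif(sqrt(sum(r^2)) / bnrm, 3), ")")
  x
}

# central gradient of a 3D array along dim, one-sided at the ends (spacing d)
cgrad <- function(a, d, dim) {
  n <- dim(a)[dim]
  if (n == 1) return(array(0, dim(a)))
  idx <- function(k) switch(dim,
    a[k, , , drop = FALSE], a[, k, , drop = FALSE], a[, , k, drop = FALSE])
  g <- array(0, dim(a))
  asg <- function(g, k, val) {
    switch(dim, g[k, , ] <- val, g[, k, ] <- val, g[, , k] <- val); g
  }
  for (k in seq_len(n)) {
    if (k == 1) v <- (idx(2) - idx(1)) / d
    else if (k == n) v <- (idx(n) - idx(n - 1)) / d
    else v <- (idx(k + 1) - idx(k - 1)) / (2 * d)
    g <- asg(g, k, v)
  }
  g
}

#' Steady non-Newtonian flow through the thin blood chamber
#'
#' Finite-volume solution of steady incompressible momentum balance with
#' Carreau apparent viscosity on a layered thin-gap grid: the in-plane
#' velocity components are staggered (MAC) and resolved on every z-layer,
#' the pressure is a single field per grid column (consistent with the
#' lubrication limit of a chamber 20x thinner than wide), and the
#' through-thickness velocity is reconstructed from cell-wise continuity, so
#' the discrete divergence is zero in every cell by construction. The
#' nonlinear viscosity (and, optionally, upwinded inertia) is handled by
#' Picard iteration; each iteration solves the saddle-point system through a
#' pressure Schur complement (sparse-LU momentum blocks, BiCGSTAB on the
#' reduced pressure system preconditioned by the lubrication operator).
#' Inlet and outlet tubes are represented as flux patches on the
#' bottom/top faces; their own pressure drop is added analytically by
#' [tube_pressure_drop()] in [flow_metrics()].
#'
#' @param grid a [build_grid()] result built with `include_shell = FALSE`.
#' @param rheology a [blood_rheology()].
#' @param bc a [flow_bc()].
#' @param inertia include the upwinded convective term (Picard-lagged);
#'   `FALSE` gives Stokes flow (used by verification fixtures).
#' @param tol Picard convergence tolerance on the relative velocity change.
#' @param max_iter maximum Picard iterations.
#' @param relax Picard under-relaxation factor on the velocity update
#'   (stabilizes the convective coupling at high flow rates).
#' @param init optional previous `flow_field` on the same grid used as a
#'   warm start (velocities scaled by the flow-rate ratio).
#' @param quiet suppress iteration messages.
#' @return object of class `flow_field` with face velocities `u`, `v`, `w`
#'   (m/s), cell-centred `Uc`, `Vc`, `Wc`, column pressure `p` (Pa), shear
#'   rate `gdot` (1/s), apparent viscosity `mu` (Pa s), convergence history
#'   and mass-balance diagnostics.
#' @export
solve_flow <- function(grid, rheology = blood_rheology(), bc,
                       inertia = TRUE, tol = 1e-3, max_iter = 25,
                       relax = if (inertia) 0.7 else 1, init = NULL,
                       quiet = TRUE) {
  spec <- grid$spec
  if (grid$include_shell)
    stop("flow grid must be built with include_shell = FALSE", call. = FALSE)
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  M <- grid$mask[, , 1] == 1L
  if (!any(M)) stop("grid has no blood cells", call. = FALSE)
  dx <- grid$dx / 100; dy <- grid$dy / 100
  dz <- grid$dzc[1] / 100
  h <- spec$chamber_height / 100
  rho <- rheology$density
  Q <- bc$Q

  # ---- port patches / channel boundary values -------------------------------
  uk <- array(0, c(nx + 1, ny, nz))   # known (boundary) u values
  vk <- array(0, c(nx, ny + 1, nz))
  qin_col <- matrix(0, nx, ny); qout_col <- matrix(0, nx, ny)
  if (bc$type == "ports") {
    pp <- port_positions(spec)
    rad <- spec$tube_inner_diameter / 2
    pin <- port_patch(grid, pp$inlet, rad)
    pout <- port_patch(grid, pp$outlet, rad)
    bad <- !M[cbind(pin$i, pin$j)] | !M[cbind(pout$i, pout$j)]
    if (any(bad)) stop("disconnected ports: port patch overlaps non-blood cells")
    qin_col[cbind(pin$i, pin$j)] <- Q * pin$frac
    qout_col[cbind(pout$i, pout$j)] <- Q * pout$frac
    pin_col <- c(pout$i[which.max(pout$frac)], pout$j[which.max(pout$frac)])
  } else {
    jin <- which(M[1, ]); jout <- which(M[nx, ])
    Uin <- Q / (length(jin) * dy * h)
    uk[1, jin, ] <- Uin
    uk[nx + 1, jout, ] <- Q / (length(jout) * dy * h)
    pin_col <- c(nx, jout[1])
  }

  # ---- unknown numbering ----------------------------------------------------
  MU2 <- M[-nx, , drop = FALSE] & M[-1, , drop = FALSE]    # (nx-1, ny)
  MV2 <- M[, -ny, drop = FALSE] & M[, -1, drop = FALSE]    # (nx, ny-1)
  maskU <- array(FALSE, c(nx + 1, ny, nz))
  maskU[2:nx, , ] <- array(MU2, c(nx - 1, ny, nz))
  maskV <- array(FALSE, c(nx, ny + 1, nz))
  maskV[, 2:ny, ] <- array(MV2, c(nx, ny - 1, nz))
  iu <- array(0L, dim(maskU)); iu[maskU] <- seq_len(sum(maskU))
  iv <- array(0L, dim(maskV)); iv[maskV] <- seq_len(sum(maskV))
  nu <- sum(maskU); nv <- sum(maskV)
  ip <- matrix(0L, nx, ny); ip[M] <- seq_len(sum(M))
  np <- sum(M)
  offv <- nu; offp <- nu + nv

  faceU <- arrayInd(which(maskU), dim(maskU))
  faceV <- arrayInd(which(maskV), dim(maskV))
  cols2 <- arrayInd(which(M), dim(M))
  ip_pin <- ip[pin_col[1], pin_col[2]]

  # safe array lookup returning `fill` when any index is out of range
  safe <- function(arr, i, j, k, fill = 0) {
    d <- dim(arr)
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- rep(fill, length(i))
    if (any(ok)) out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
    out
  }

  momentum_triplets <- function(comp, mu, Up, Vp, Wp) {
    # comp: "u" or "v"; returns triplets of the momentum block row
    if (comp == "u") {
      f <- faceU; idn <- iu; known <- uk; roff <- 0L
      dn <- dx   # normal spacing for pressure gradient
    } else {
      f <- faceV; idn <- iv; known <- vk; roff <- offv
      dn <- dy
    }
    i <- f[, 1]; j <- f[, 2]; k <- f[, 3]
    nf <- nrow(f)
    row <- seq_len(nf) + roff
    if (comp == "u") {
      muf <- 0.5 * (mu[cbind(i - 1, j, k)] + mu[cbind(i, j, k)])
      Uf <- Up[cbind(i, j, k)]
      Vf <- 0.25 * (safe(Vp, i - 1, j, k) + safe(Vp, i - 1, j + 1, k) +
                    safe(Vp, i, j, k) + safe(Vp, i, j + 1, k))
      Wf <- 0.25 * (safe(Wp, i - 1, j, k) + safe(Wp, i - 1, j, k + 1) +
                    safe(Wp, i, j, k) + safe(Wp, i, j, k + 1))
    } else {
      muf <- 0.5 * (mu[cbind(i, j - 1, k)] + mu[cbind(i, j, k)])
      Vf <- Vp[cbind(i, j, k)]
      Uf <- 0.25 * (safe(Up, i, j - 1, k) + safe(Up, i + 1, j - 1, k) +
                    safe(Up, i, j, k) + safe(Up, i + 1, j, k))
      Wf <- 0.25 * (safe(Wp, i, j - 1, k) + safe(Wp, i, j - 1, k + 1) +
                    safe(Wp, i, j, k) + safe(Wp, i, j, k + 1))
    }
    if (!inertia) { Uf <- Uf * 0; Vf <- Vf * 0; Wf <- Wf * 0 }
    axm <- muf / dx^2 + rho * pmax(Uf, 0) / dx
    axp <- muf / dx^2 - rho * pmin(Uf, 0) / dx
    aym <- muf / dy^2 + rho * pmax(Vf, 0) / dy
    ayp <- muf / dy^2 - rho * pmin(Vf, 0) / dy
    azm <- ifelse(k == 1, 2, 1) * muf / dz^2 + rho * pmax(Wf, 0) / dz
    azp <- ifelse(k == nz, 2, 1) * muf / dz^2 - rho * pmin(Wf, 0) / dz
    diag <- axm + axp + aym + ayp + azm + azp
    ti <- row; tj <- row; tx <- diag
    rhs <- numeric(nf)
    add_nb <- function(di, dj, dk, a) {
      ni <- i + di; nj <- j + dj; nk <- k + dk
      d <- dim(idn)
      inb <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
      nid <- rep(0L, nf)
      nid[inb] <- idn[cbind(ni[inb], nj[inb], nk[inb])]
      unk <- nid > 0
      if (any(unk)) {
        ti <<- c(ti, row[unk]); tj <<- c(tj, nid[unk] + roff)
        tx <<- c(tx, -a[unk])
      }
      bnd <- !unk & inb
      if (any(bnd)) {
        kv <- known[cbind(ni[bnd], nj[bnd], nk[bnd])]
        nzv <- kv != 0
        if (any(nzv)) rhs[which(bnd)[nzv]] <<- rhs[which(bnd)[nzv]] +
            a[bnd][nzv] * kv[nzv]
      }
      # z-walls (nk out of range) are plain no-slip zeros: diagonal only
    }
    add_nb(-1L, 0L, 0L, axm); add_nb(1L, 0L, 0L, axp)
    add_nb(0L, -1L, 0L, aym); add_nb(0L, 1L, 0L, ayp)
    add_nb(0L, 0L, -1L, azm); add_nb(0L, 0L, 1L, azp)
    # pressure gradient
    if (comp == "u") {
      pE <- ip[cbind(i, j)]; pW <- ip[cbind(i - 1, j)]
    } else {
      pE <- ip[cbind(i, j)]; pW <- ip[cbind(i, j - 1)]
    }
    ti <- c(ti, row, row)
    tj <- c(tj, pE + offp, pW + offp)
    tx <- c(tx, rep(1 / dn, nf), rep(-1 / dn, nf))
    list(i = ti, j = tj, x = tx, rhs = rhs, row = row)
  }

  continuity_triplets <- function() {
    ci <- cols2[, 1]; cj <- cols2[, 2]
    ncl <- nrow(cols2)
    row <- offp + seq_len(ncl)
    sc <- 1 / (dx * h)          # row scaling for conditioning
    ti <- integer(0); tj <- integer(0); tx <- numeric(0)
    rhs <- (qin_col[cbind(ci, cj)] - qout_col[cbind(ci, cj)]) * sc
    for (k in seq_len(nz)) {
      a <- dz * dy * sc
      for (side in list(list(di = 1L, sgn = +1), list(di = 0L, sgn = -1))) {
        fid <- iu[cbind(ci + side$di, cj, k)]
        unk <- fid > 0
        ti <- c(ti, row[unk]); tj <- c(tj, fid[unk])
        tx <- c(tx, rep(side$sgn * a, sum(unk)))
        kv <- uk[cbind(ci + side$di, cj, k)]
        bnd <- !unk & kv != 0
        rhs[bnd] <- rhs[bnd] - side$sgn * a * kv[bnd]
      }
      a <- dz * dx * sc
      for (side in list(list(dj = 1L, sgn = +1), list(dj = 0L, sgn = -1))) {
        fid <- iv[cbind(ci, cj + side$dj, k)]
        unk <- fid > 0
        ti <- c(ti, row[unk]); tj <- c(tj, fid[unk] + offv)
        tx <- c(tx, rep(side$sgn * a, sum(unk)))
        kv <- vk[cbind(ci, cj + side$dj, k)]
        bnd <- !unk & kv != 0
        rhs[bnd] <- rhs[bnd] - side$sgn * a * kv[bnd]
      }
    }
    list(i = ti, j = tj, x = tx, rhs = rhs, row = row)
  }

  reconstruct_w <- function(uarr, varr) {
    w <- array(0, c(nx, ny, nz + 1))
    w[, , 1] <- qin_col / (dx * dy)
    for (k in seq_len(nz)) {
      div <- (uarr[2:(nx + 1), , k] - uarr[1:nx, , k]) * dz * dy +
             (varr[, 2:(ny + 1), k] - varr[, 1:ny, k]) * dz * dx
      w[, , k + 1] <- w[, , k] - div / (dx * dy)
    }
    w
  }

  # ---- Picard loop ----------------------------------------------------------
  # Each iteration solves the saddle-point system by a pressure Schur
  # complement: the two momentum blocks are factorized (sparse LU) and the
  # reduced pressure system is solved by BiCGSTAB, warm-started from the
  # previous iteration.
  uarr <- array(0, c(nx + 1, ny, nz)); uarr[] <- uk
  varr <- array(0, c(nx, ny + 1, nz)); varr[] <- vk
  warr <- reconstruct_w(uarr, varr) * 0
  mu <- array(carreau_viscosity(10, rheology), c(nx, ny, nz))
  if (!is.null(init)) {
    sc_init <- bc$Q / max(init$bc$Q, 1e-30)
    if (all(dim(init$u) == dim(uarr))) {
      uarr <- init$u * sc_init; varr <- init$v * sc_init
      warr <- init$w * sc_init; mu <- init$mu
    }
  }
  hist <- numeric(0)
  converged <- FALSE
  pr_keep <- setdiff(seq_len(np), ip_pin)
  p_red <- numeric(np - 1)
  for (it in seq_len(max_iter)) {
    tu <- momentum_triplets("u", mu, uarr, varr, warr)
    tv <- momentum_triplets("v", mu, uarr, varr, warr)
    tc <- continuity_triplets()
    isGu <- tu$j > offp
    Au <- Matrix::sparseMatrix(i = tu$i[!isGu], j = tu$j[!isGu],
                               x = tu$x[!isGu], dims = c(nu, nu))
    Gu <- Matrix::sparseMatrix(i = tu$i[isGu], j = tu$j[isGu] - offp,
                               x = tu$x[isGu], dims = c(nu, np))
    isGv <- tv$j > offp
    Av <- Matrix::sparseMatrix(i = tv$i[!isGv] - offv,
                               j = tv$j[!isGv] - offv,
                               x = tv$x[!isGv], dims = c(nv, nv))
    Gv <- Matrix::sparseMatrix(i = tv$i[isGv] - offv, j = tv$j[isGv] - offp,
                               x = tv$x[isGv], dims = c(nv, np))
    isDu <- tc$j <= nu
    Du <- Matrix::sparseMatrix(i = tc$i[isDu] - offp, j = tc$j[isDu],
                               x = tc$x[isDu], dims = c(np, nu))
    Dv <- Matrix::sparseMatrix(i = tc$i[!isDu] - offp, j = tc$j[!isDu] - offv,
                               x = tc$x[!isDu], dims = c(np, nv))
    fu <- tu$rhs - as.numeric(Gu[, ip_pin]) * bc$outlet_pressure
    fv <- tv$rhs - as.numeric(Gv[, ip_pin]) * bc$outlet_pressure
    gc_rhs <- tc$rhs
    Fu <- Matrix::lu(Au); Fv <- Matrix::lu(Av)
    Gur <- Gu[, pr_keep, drop = FALSE]; Gvr <- Gv[, pr_keep, drop = FALSE]
    Dur <- Du[pr_keep, , drop = FALSE]; Dvr <- Dv[pr_keep, , drop = FALSE]
    msolve <- function(F, b) as.numeric(Matrix::solve(F, b))
    bS <- as.numeric(Dur %*% msolve(Fu, fu) + Dvr %*% msolve(Fv, fv)) -
      gc_rhs[pr_keep]
    opS <- function(pv)
      as.numeric(Dur %*% msolve(Fu, as.numeric(Gur %*% pv)) +
                 Dvr %*% msolve(Fv, as.numeric(Gvr %*% pv)))
    # lubrication preconditioner: S0 = div (h^3 / 12 mu) grad on columns
    mubar <- matrix(0, nx, ny)
    for (k in seq_len(nz)) mubar <- mubar + mu[, , k] / nz
    s0i <- integer(0); s0j <- integer(0); s0x <- numeric(0)
    sc0 <- 1 / (dx * h)
    add_face <- function(c1i, c1j, c2i, c2j) {
      id1 <- ip[cbind(c1i, c1j)]; id2 <- ip[cbind(c2i, c2j)]
      ok <- id1 > 0 & id2 > 0
      id1 <- id1[ok]; id2 <- id2[ok]
      muf2 <- 0.5 * (mubar[cbind(c1i, c1j)] + mubar[cbind(c2i, c2j)])[ok]
      t <- sc0 * dy * h^3 / (12 * muf2 * dx)
      s0i <<- c(s0i, id1, id2, id1, id2)
      s0j <<- c(s0j, id1, id2, id2, id1)
      s0x <<- c(s0x, t, t, -t, -t)
    }
    ii2 <- cols2[cols2[, 1] < nx, , drop = FALSE]
    add_face(ii2[, 1], ii2[, 2], ii2[, 1] + 1L, ii2[, 2])
    jj2 <- cols2[cols2[, 2] < ny, , drop = FALSE]
    add_face(jj2[, 1], jj2[, 2], jj2[, 1], jj2[, 2] + 1L)
    S0 <- Matrix::sparseMatrix(i = s0i, j = s0j, x = s0x, dims = c(np, np))
    S0 <- S0 + Matrix::Diagonal(np, max(abs(s0x)) * 1e-10)
    S0r <- S0[pr_keep, pr_keep, drop = FALSE]
    F0 <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(S0r), "CsparseMatrix"),
                           LDL = FALSE, perm = TRUE)
    prec <- function(y) as.numeric(Matrix::solve(F0, y, system = "A"))
    yb <- bicgstab(function(y) opS(prec(y)), bS,
                   x0 = as.numeric(S0r %*% p_red), tol = 1e-10, maxit = 400)
    p_red <- prec(yb)
    usol <- msolve(Fu, fu - as.numeric(Gur %*% p_red))
    vsol <- msolve(Fv, fv - as.numeric(Gvr %*% p_red))
    pfull <- numeric(np)
    pfull[pr_keep] <- p_red; pfull[ip_pin] <- bc$outlet_pressure
    unew <- array(0, dim(uarr)); unew[] <- uk; unew[maskU] <- usol
    vnew <- array(0, dim(varr)); vnew[] <- vk; vnew[maskV] <- vsol
    p2 <- matrix(0, nx, ny); p2[M] <- pfull
    if (relax < 1 && it > 1) {   # linear relaxation preserves continuity
      unew <- relax * unew + (1 - relax) * uarr
      vnew <- relax * vnew + (1 - relax) * varr
    }
    wnew <- reconstruct_w(unew, vnew)
    du <- max(abs(unew - uarr), abs(vnew - varr))
    scale_u <- max(abs(unew), abs(vnew), abs(wnew), 1e-30)
    hist <- c(hist, du / scale_u)
    uarr <- unew; varr <- vnew; warr <- wnew
    # update viscosity from the shear-rate field
    Uc <- 0.5 * (uarr[1:nx, , , drop = FALSE] + uarr[2:(nx + 1), , , drop = FALSE])
    Vc <- 0.5 * (varr[, 1:ny, , drop = FALSE] + varr[, 2:(ny + 1), , drop = FALSE])
    Wc <- 0.5 * (warr[, , 1:nz, drop = FALSE] + warr[, , 2:(nz + 1), drop = FALSE])
    gdot <- shear_rate_field(uarr, varr, warr, Uc, Vc, Wc, dx, dy, dz, nx, ny, nz)
    munew <- array(carreau_viscosity(as.vector(gdot), rheology), dim(mu))
    mu <- 0.5 * mu + 0.5 * munew
    if (!quiet) message(sprintf("picard %d: rel du = %.3e", it, utils::tail(hist, 1)))
    if (it >= 3 && utils::tail(hist, 1) < tol) { converged <- TRUE; break }
  }
  if (!converged && utils::tail(hist, 1) > 10 * tol)
    stop(sprintf(
      "flow solver did not converge in %d iterations (last rel change %.2e); history: %s",
      max_iter, utils::tail(hist, 1), paste(signif(hist, 3), collapse = " ")),
      call. = FALSE)

  # global balance: reconstructed top-face outflow vs the imposed patches
  mass_err <- if (bc$type == "ports") {
    sum(abs(warr[, , nz + 1] * dx * dy - qout_col)[M]) / max(Q, 1e-30)
  } else 0

  structure(list(
    grid = grid, spec = spec, rheology = rheology, bc = bc,
    u = uarr, v = varr, w = warr,
    Uc = array(Uc, c(nx, ny, nz)), Vc = array(Vc, c(nx, ny, nz)),
    Wc = array(Wc, c(nx, ny, nz)),
    p = p2, mu = mu, gdot = gdot,
    mask2d = M, qin_col = qin_col, qout_col = qout_col,
    dx_m = dx, dy_m = dy, dz_m = dz,
    iterations = it, history = hist, converged = converged,
    mass_balance_error = mass_err
  ), class = "flow_field")
}

shear_rate_field <- function(u, v, w, Uc, Vc, Wc, dx, dy, dz, nx, ny, nz) {
  dudx <- (u[2:(nx + 1), , , drop = FALSE] - u[1:nx, , , drop = FALSE]) / dx
  dvdy <- (v[, 2:(ny + 1), , drop = FALSE] - v[, 1:ny, , drop = FALSE]) / dy
  dwdz <- (w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE]) / dz
  Uc <- array(Uc, c(nx, ny, nz)); Vc <- array(Vc, c(nx, ny, nz))
  Wc <- array(Wc, c(nx, ny, nz))
  # z derivatives with mirror ghosts (no-slip walls)
  padz <- function(a) {
    g <- array(0, c(nx, ny, nz + 2))
    g[, , 2:(nz + 1)] <- a
    g[, , 1] <- -a[, , 1]; g[, , nz + 2] <- -a[, , nz]
    g
  }
  dz2 <- function(g) (g[, , 3:(nz + 2), drop = FALSE] -
                      g[, , 1:nz, drop = FALSE]) / (2 * dz)
  dudz <- dz2(padz(Uc)); dvdz <- dz2(padz(Vc))
  dudy <- cgrad(Uc, dy, 2); dvdx <- cgrad(Vc, dx, 1)
  dwdx <- cgrad(Wc, dx, 1); dwdy <- cgrad(Wc, dy, 2)
  sqrt(2 * (dudx^2 + dvdy^2 + dwdz^2) +
       (dudy + dvdx)^2 + (dudz + dwdx)^2 + (dvdz + dwdy)^2)
}

#' Maximum cell-wise continuity residual of a flow field
#'
#' Net volumetric imbalance of every blood cell relative to the inlet flow
#' (zero to round-off by construction of the through-thickness velocity).
#'
#' @param field a [solve_flow()] result.
#' @return maximum relative divergence residual.
#' @export
flow_divergence <- function(field) {
  nx <- dim(field$Uc)[1]; ny <- dim(field$Uc)[2]; nz <- dim(field$Uc)[3]
  dx <- field$dx_m; dy <- field$dy_m; dz <- field$dz_m
  res <- 0
  for (k in seq_len(nz)) {
    # boundary z-faces already carry the port fluxes; at k = nz the
    # reconstructed top-face flux must additionally match the outlet patch,
    # which is the true residual of the pressure (continuity) solve
    wtop <- if (k == nz) field$qout_col / (dx * dy) else field$w[, , k + 1]
    div <- (field$u[2:(nx + 1), , k] - field$u[1:nx, , k]) * dz * dy +
           (field$v[, 2:(ny + 1), k] - field$v[, 1:ny, k]) * dz * dx +
           (wtop - field$w[, , k]) * dx * dy
    res <- max(res, max(abs(div)[field$mask2d]))
  }
  res / max(field$bc$Q, 1e-30)
}

#' Analytic tube (Poiseuille) pressure drop of both port stubs
#'
#' Laminar fully developed pipe flow with the Carreau viscosity evaluated at
#' the nominal wall shear rate `8 V / d`. Both tubes (each spanning the stub
#' height plus the plexiglass wall) are included.
#'
#' @param flow_rate_lpm flow rate, L/min.
#' @param spec a [device_spec()].
#' @param rheology a [blood_rheology()].
#' @return pressure drop in Pa (sum over the two tubes).
#' @export
tube_pressure_drop <- function(flow_rate_lpm, spec, rheology = blood_rheology()) {
  Q <- flow_rate_lpm * 1e-3 / 60
  d <- spec$tube_inner_diameter / 100
  L <- (spec$tube_height + spec$plexiglass_thickness) / 100
  V <- Q / (pi * (d / 2)^2)
  mu <- carreau_viscosity(8 * V / d, rheology)
  2 * 128 * mu * L * Q / (pi * d^4)
}

#' Mean tube velocity from the flow rate and bore
#'
#' @inheritParams tube_pressure_drop
#' @return mean velocity in mm/s.
#' @export
tube_mean_velocity <- function(flow_rate_lpm, spec) {
  Q <- flow_rate_lpm * 1e-3 / 60
  d <- spec$tube_inner_diameter / 100
  1e3 * Q / (pi * (d / 2)^2)
}

#' Resolved axial flow in a circular tube cross-section
#'
#' Solves the axial Poisson problem on a rasterized disc (unit pressure
#' gradient, then rescaled to the requested flow rate); used to verify the
#' tube mean velocity against `Q / A` at finite resolution.
#'
#' @param flow_rate_lpm flow rate, L/min.
#' @param diameter bore, cm.
#' @param n_across cells across the diameter.
#' @return list with `mean_mm_s`, `max_mm_s`, `area_cm2`.
#' @export
solve_tube_flow <- function(flow_rate_lpm, diameter = 1.27, n_across = 8) {
  Q <- flow_rate_lpm * 1e-3 / 60
  dxc <- diameter / n_across / 100
  nc <- n_across + 2L
  ctr <- nc / 2 * dxc
  xc <- (seq_len(nc) - 0.5) * dxc
  inside <- outer(xc, xc, function(a, b)
    (a - ctr)^2 + (b - ctr)^2 < (diameter / 200)^2)
  id <- matrix(0L, nc, nc); id[inside] <- seq_len(sum(inside))
  n <- sum(inside)
  idx <- which(inside, arr.ind = TRUE)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  row <- id[inside]
  diagv <- rep(0, n)
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    ni <- idx[, 1] + d[1]; nj <- idx[, 2] + d[2]
    ok <- ni >= 1 & ni <= nc & nj >= 1 & nj <= nc
    nid <- rep(0L, n); nid[ok] <- id[cbind(ni[ok], nj[ok])]
    unk <- nid > 0
    ti <- c(ti, row[unk]); tj <- c(tj, nid[unk]); tx <- c(tx, rep(-1, sum(unk)))
    diagv <- diagv + ifelse(unk, 1, 2)   # wall at half-spacing
  }
  A <- Matrix::sparseMatrix(i = c(ti, row), j = c(tj, row),
                            x = c(tx, diagv), dims = c(n, n)) / dxc^2
  uraw <- as.numeric(Matrix::solve(A, rep(1, n)))
  area <- n * dxc^2
  scale <- Q / (sum(uraw) * dxc^2)
  u <- uraw * scale
  list(mean_mm_s = 1e3 * mean(u), max_mm_s = 1e3 * max(u),
       area_cm2 = area * 1e4)
}

#' Flow summary metrics (velocities, pressure drop, stagnation)
#'
#' Volume-weighted mean and pointwise maximum speed over the chamber,
#' analytic tube velocities, the inlet-to-outlet pressure drop (solved
#' chamber drop plus the analytic tube drop) and the stagnation fraction.
#'
#' A grid column counts as stagnant when its depth-averaged speed falls
#' below `stagnation_threshold`; the fraction is the stagnant share of the
#' blood volume. The depth-averaged (rather than cell-wise) speed is used
#' because with a handful of uniform layers through the 1 cm gap every
#' near-wall cell of the parabolic profile would otherwise be counted,
#' swamping the actual dead zones the threshold is meant to flag; the
#' cell-wise fraction is also reported.
#'
#' @param field a [solve_flow()] result.
#' @param spec the device spec (defaults to the field's).
#' @param stagnation_threshold speed threshold, mm/s.
#' @return object of class `flow_metrics` (a one-row data.frame).
#' @export
flow_metrics <- function(field, spec = field$spec, stagnation_threshold = 1) {
  sp <- sqrt(field$Uc^2 + field$Vc^2 + field$Wc^2)
  msk <- array(field$mask2d, dim(sp))
  spd <- sp[msk] * 1e3                      # mm/s
  nz <- dim(sp)[3]
  Ub <- apply(field$Uc, c(1, 2), mean)
  Vb <- apply(field$Vc, c(1, 2), mean)
  Wb <- apply(field$Wc, c(1, 2), mean)
  spd_bar <- sqrt(Ub^2 + Vb^2 + Wb^2)[field$mask2d] * 1e3
  rate <- field$bc$flow_rate_lpm
  v_tube <- tube_mean_velocity(rate, spec)
  dp_cham <- sum(field$p[field$qin_col > 0] *
                 field$qin_col[field$qin_col > 0]) / sum(field$qin_col) -
             field$bc$outlet_pressure
  dp_tube <- tube_pressure_drop(rate, spec, field$rheology)
  out <- data.frame(
    flow_rate_lpm = rate,
    avg_chamber_mm_s = mean(spd),
    max_chamber_mm_s = max(spd),
    avg_tube_mm_s = v_tube,
    max_tube_mm_s = 2 * v_tube,             # parabolic centreline
    dp_chamber_Pa = dp_cham,
    dp_tube_Pa = dp_tube,
    dp_total_Pa = dp_cham + dp_tube,
    stagnation_fraction = mean(spd_bar < stagnation_threshold),
    stagnation_fraction_cells = mean(spd < stagnation_threshold),
    fillet_radius = spec$fillet_radius
  )
  class(out) <- c("flow_metrics", class(out))
  out
}
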