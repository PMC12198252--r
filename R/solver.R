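#' Solve the pulsatile lumped-parameter PA network
#'
#' The tree is modelled as a resistive network: each segment contributes its
#' Poiseuille resistance `R_seg = 8 mu L / (pi r^4)`, junctions are
#' pressure-continuous and loss-free, walls are rigid, and each outlet
#' terminates in a three-element Windkessel. The prescribed periodic inflow
#' drives the network for `n_cycles` cardiac cycles (six by default, so the
#' solution settles to its periodic state) and indices are computed from the
#' last cycle.
#'
#' The Windkessel capacitor pressures are the only states; they obey
#' `C dPc/dt = Q_outlet - (Pc - Pd)/Rd`, with the outlet flows recovered at
#' every instant from the linear resistive network and the flow constraint
#' `sum(Q_outlet) = Q_in(t)`. Integration uses `deSolve::lsoda` with tight
#' tolerances and a fixed output grid.
#'
#' @param tree A [pa_tree()].
#' @param rcr_set Named list of [windkessel_rcr()], one per outlet id.
#' @param inflow A [flow_waveform()].
#' @param fluid A [fluid_properties()].
#' @param n_cycles Number of cardiac cycles to simulate (default 6).
#' @param steps_per_cycle Output samples per cycle (default 256).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `network_solution`: `time` (full grid),
#'   `inlet_flow`, `inlet_pressure`, `outlet_ids`, `outlet_flow` /
#'   `outlet_pressure` / `capacitor_pressure` (matrices, time x outlet;
#'   `outlet_pressure` is the pressure at the outlet cap, upstream of Rp),
#'   `segment_flow` (time x segment), `last_cycle` (row indices),
#'   `periodicity_defect` (max relative change of outlet cycle volumes,
#'   last vs previous cycle), `period`.
#' @export
solve_network <- function(tree, rcr_set, inflow, fluid = fluid_properties(),
                          n_cycles = 6L, steps_per_cycle = 256L,
                          rtol = 1e-8, atol = 1e-10) {
  seg <- tree$segments
  if (any(seg$radius <= 0)) stop("singular network: zero-radius segment")
  outs <- outlet_ids(tree)
  if (!all(as.character(outs) %in% names(rcr_set))) {
    stop("every outlet needs an RCR model (missing: ",
         paste(setdiff(as.character(outs), names(rcr_set)), collapse = ", "), ")")
  }
  rcr <- rcr_set[as.character(outs)]
  n_out <- length(outs)
  mu <- fluid$viscosity
  r_seg <- 8 * mu * seg$length / (pi * seg$radius^4)
  names(r_seg) <- seg$id

  # paths from root to each outlet; shared-resistance matrix M
  paths <- lapply(outs, function(o) path_to_root(tree, o))
  M <- matrix(0, n_out, n_out)
  for (i in seq_len(n_out)) {
    for (j in seq_len(n_out)) {
      shared <- intersect(paths[[i]], paths[[j]])
      M[i, j] <- sum(r_seg[as.character(shared)])
    }
  }
  Rp <- vapply(rcr, `[[`, numeric(1), "Rp")
  Rd <- vapply(rcr, `[[`, numeric(1), "Rd")
  Cc <- vapply(rcr, `[[`, numeric(1), "C")
  Pd <- vapply(rcr, `[[`, numeric(1), "Pd")
  diag(M) <- diag(M) + Rp
  A <- solve(M)                       # conductance form: Q = A (P_in - Pc)
  a_row <- rowSums(A)
  a_tot <- sum(a_row)

  qin_fun <- periodic_interpolant(inflow)
  T <- inflow$period

  flows_at <- function(qin, pc) {
    p_in <- (qin + sum(A %*% pc)) / a_tot
    q <- as.vector(A %*% (p_in - pc))
    list(p_in = p_in, q = q)
  }

  rhs <- function(t, y, parms) {
    fl <- flows_at(qin_fun(t), y)
    list((fl$q - (y - Pd) / Rd) / Cc)
  }

  # initial condition: steady state under the cycle-mean inflow
  q_mean <- cycle_mean(inflow$time, inflow$flow, T)
  Ms <- M + diag(Rd, n_out)
  As <- solve(Ms)
  # choose P_in so that total steady flow equals q_mean (relative to Pd)
  g_row <- rowSums(As)
  p_in0 <- q_mean / sum(g_row)
  q0 <- as.vector(As %*% rep(p_in0, n_out))   # uniform Pd offset cancels
  pc0 <- Pd + Rd * q0

  t_out <- seq(0, n_cycles * T, by = T / steps_per_cycle)
  sol <- deSolve::lsoda(y = pc0, times = t_out, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integrator failure in solve_network (istate = ",
         attr(sol, "istate")[1], ")")
  }
  pc <- unname(sol[, -1, drop = FALSE])
  nt <- length(t_out)
  qin <- qin_fun(t_out)
  # recover algebraic quantities on the output grid
  p_in <- (qin + as.vector(pc %*% a_row)) / a_tot
  q_out <- (matrix(p_in, nt, n_out) - pc) %*% t(A)
  p_cap <- pc + q_out * matrix(Rp, nt, n_out, byrow = TRUE)

  # per-segment flow: sum of outlet flows whose path contains the segment
  inc <- vapply(seq_len(n_out), function(i) seg$id %in% paths[[i]],
                logical(nrow(seg)))
  segq <- q_out %*% t(inc * 1)
  colnames(segq) <- seg$id
  colnames(q_out) <- colnames(p_cap) <- colnames(pc) <- as.character(outs)

  last <- which(t_out > (n_cycles - 1) * T - 1e-12 * T)
  prev <- which(t_out > (n_cycles - 2) * T - 1e-12 * T &
                  t_out <= (n_cycles - 1) * T + 1e-12 * T)
  vol_last <- apply(q_out[last, , drop = FALSE], 2, trapz_rows, t_out[last])
  vol_prev <- apply(q_out[prev, , drop = FALSE], 2, trapz_rows, t_out[prev])
  defect <- max(abs(vol_last - vol_prev) / pmax(abs(vol_last), 1e-12))

  structure(list(
    time = t_out, inlet_flow = qin, inlet_pressure = p_in,
    outlet_ids = outs, outlet_flow = q_out, outlet_pressure = p_cap,
    capacitor_pressure = pc, segment_flow = segq,
    last_cycle = last, periodicity_defect = defect,
    period = T, n_cycles = n_cycles, fluid = fluid,
    segment_resistance = r_seg
  ), class = "network_solution")
}

trapz_rows <- function(y, x) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf(
    "Network solution: %d cycles of T = %g s, %d outlets, periodicity defect %.2e\n",
    x$n_cycles, x$period, length(x$outlet_ids), x$periodicity_defect))
  invisible(x)
}

#' Extract the last simulated cycle
#'
#' @param sol A `network_solution`.
#' @return List with `time` (shifted to start at 0, length
#'   `steps_per_cycle + 1`, closed interval including the wrap point),
#'   `inlet_flow`, `inlet_pressure`, `outlet_flow`, `outlet_pressure`,
#'   `segment_flow`.
#' @export
last_cycle <- function(sol) {
  i <- sol$last_cycle
  list(time = sol$time[i] - sol$time[i[1]],
       inlet_flow = sol$inlet_flow[i],
       inlet_pressure = sol$inlet_pressure[i],
       outlet_flow = sol$outlet_flow[i, , drop = FALSE],
       outlet_pressure = sol$outlet_pressure[i, , drop = FALSE],
       segment_flow = sol$segment_flow[i, , drop = FALSE])
}

# cycle volume through a segment over the last cycle (mL)
segment_cycle_volume <- function(sol, segment_id) {
  lc <- last_cycle(sol)
  trapz_rows(lc$segment_flow[, as.character(segment_id)], lc$time)
}

# last-cycle flow waveform of one segment (drops the duplicated wrap sample)
segment_waveform <- function(sol, segment_id) {
  lc <- last_cycle(sol)
  n <- length(lc$time) - 1L
  flow_waveform(lc$time[seq_len(n)],
                lc$segment_flow[seq_len(n), as.character(segment_id)],
                period = sol$period)
}

#' Export a network solution as a tidy table
#'
#' @param sol A `network_solution`.
#' @return `data.frame` with columns `time`, `segment`, `flow`
#'   (plus `pressure` for the inlet and outlet caps where defined).
#' @export
solution_to_table <- function(sol) {
  seg_ids <- colnames(sol$segment_flow)
  do.call(rbind, lapply(seg_ids, function(s) {
    data.frame(time = sol$time, segment = as.integer(s),
               flow = sol$segment_flow[, s])
  }))
}

# --- Womersley / Poiseuille in-segment velocity profiles ---------------------

#' Analytic pulsatile velocity profile in a segment
#'
#' Reconstructs the axisymmetric axial velocity field `u(s, t)` in a rigid
#' circular segment carrying the given flow waveform. The waveform is
#' decomposed into Fourier harmonics: harmonic 0 maps to the steady Poiseuille
#' parabola, and each harmonic k >= 1 to the oscillatory (Womersley) solution
#' of the radial momentum equation
#' `i omega rho u = G + mu (u'' + u'/s)`, `u(R) = 0`, `u'(0) = 0`,
#' whose shape is the classical Bessel-function profile. Each harmonic is
#' solved on the radial grid by a second-order finite-difference scheme
#' (numerically robust at every Womersley number) and scaled so its sectional
#' flow `2 pi int u s ds` reproduces that harmonic's Fourier coefficient
#' under the same discrete quadrature. The Fourier remainder beyond
#' `n_harmonics` (waveforms with derivative kinks converge slowly) is carried
#' by default as a quasi-static parabolic correction, so the reconstructed
#' sectional flow reproduces `Q(t)` exactly at every time sample; set
#' `residual = "none"` for the pure truncated-harmonic field.
#'
#' @param segment Either a segment row of a [pa_tree()] (`data.frame` with a
#'   `radius` column) or a single positive radius in cm.
#' @param flow A [flow_waveform()] (one cycle).
#' @param fluid A [fluid_properties()].
#' @param n_harmonics Number of oscillatory harmonics retained (>= 0).
#' @param n_radial Number of radial intervals (grid has `n_radial + 1`
#'   points from the axis to the wall).
#' @param residual `"poiseuille"` (default): distribute the truncated Fourier
#'   remainder of the flow as a quasi-static parabola; `"none"`: drop it.
#' @return Object of class `velocity_field`: `s` (radial samples, cm), `u`
#'   (matrix, radial x time, cm/s), `time`, `period`, `radius`, `mode`
#'   (`"womersley"`, or `"poiseuille"` when `n_harmonics = 0`), and
#'   `womersley_numbers` (per retained harmonic).
#' @export
womersley_profile <- function(segment, flow, fluid = fluid_properties(),
                              n_harmonics = 8L, n_radial = 128L,
                              residual = c("poiseuille", "none")) {
  residual <- match.arg(residual)
  R <- if (is.numeric(segment)) segment else segment$radius
  if (length(R) != 1L || R <= 0) stop("segment radius must be a single positive number")
  if (n_harmonics < 0) stop("`n_harmonics` must be >= 0")
  q <- flow$flow
  m <- length(q)
  T <- flow$period
  K <- min(n_harmonics, floor((m - 1) / 2))
  ch <- stats::fft(q) / m              # c_k, k = 0 .. m-1

  N <- n_radial
  s <- seq(0, R, length.out = N + 1)
  h <- R / N
  nt <- m
  u <- matrix(0, N + 1, nt)

  # harmonic 0: Poiseuille
  q0 <- Re(ch[1])
  u <- u + outer(2 * q0 / (pi * R^2) * (1 - (s / R)^2), rep(1, nt))

  wo <- numeric(0)
  if (K >= 1) {
    om_base <- 2 * pi / T
    tt <- flow$time
    for (k in seq_len(K)) {
      om <- k * om_base
      wo <- c(wo, R * sqrt(om / fluid$nu))
      phi <- womersley_shape(R, om, fluid, N)    # complex profile, unit drive
      # discrete sectional flow of the shape
      Fk <- 2 * pi * trapz_rows(phi * s, s)
      ck <- ch[k + 1]
      Uk <- phi * (ck / Fk)
      u <- u + 2 * Re(outer(Uk, exp(1i * om * tt)))
    }
  }
  if (residual == "poiseuille") {
    # parabola normalized to unit *discrete* sectional flow, carrying the
    # truncated Fourier remainder so the field's flow matches Q(t) exactly
    p <- 1 - (s / R)^2
    p <- p / (2 * pi * trapz_rows(p * s, s))
    qrec <- as.vector(2 * pi * crossprod(u, s * trapz_weights(s)))
    u <- u + outer(p, q - qrec)
  }
  structure(list(s = s, u = u, time = flow$time, period = T, radius = R,
                 mode = if (K >= 1) "womersley" else "poiseuille",
                 womersley_numbers = wo,   # alpha_k = R sqrt(k omega / nu)
                 flow = flow),
            class = "velocity_field")
}

# finite-difference solve of mu (u'' + u'/s) - i om rho u = -1, u(R)=0, u'(0)=0
womersley_shape <- function(R, om, fluid, N) {
  mu <- fluid$viscosity
  rho <- fluid$density
  h <- R / N
  # unknowns u_0 .. u_{N-1} (u_N = 0 at wall); complex tridiagonal system
  n <- N
  dl <- rep(0i, n)   # sub-diagonal (rows 2..n)
  d  <- rep(0i, n)   # diagonal
  du <- rep(0i, n)   # super-diagonal (rows 1..n-1)
  b  <- rep(-1 + 0i, n) * -1          # RHS: +1 (move -1 to RHS)
  lam <- 1i * om * rho
  for (j in 0:(N - 1)) {
    i <- j + 1
    if (j == 0) {
      # axis: operator -> 4 (u1 - u0) / h^2
      d[i] <- -4 * mu / h^2 - lam
      du[i] <- 4 * mu / h^2
      b[i] <- -1
    } else {
      sj <- j * h
      d[i] <- -2 * mu / h^2 - lam
      dl[i] <- mu / h^2 - mu / (2 * sj * h)
      du[i] <- mu / h^2 + mu / (2 * sj * h)
      b[i] <- -1
    }
  }
  u <- thomas_solve(dl, d, du, b)
  c(u, 0 + 0i)
}

# Thomas algorithm for a (complex) tridiagonal system
thomas_solve <- function(dl, d, du, b) {
  n <- length(d)
  cp <- rep(0i, n); bp <- rep(0i, n)
  cp[1] <- du[1] / d[1]
  bp[1] <- b[1] / d[1]
  for (i in 2:n) {
    den <- d[i] - dl[i] * cp[i - 1]
    cp[i] <- if (i < n) du[i] / den else 0i
    bp[i] <- (b[i] - dl[i] * bp[i - 1]) / den
  }
  x <- rep(0i, n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  x
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field (%s): segment radius %.3f cm, %d radial x %d time samples\n",
              x$mode, x$radius, length(x$s), length(x$time)))
  invisible(x)
}

# discrete sectional flow of a velocity field at every time sample
field_flow <- function(field) {
  as.vector(2 * pi * crossprod(field$u, field$s * trapz_weights(field$s)))
}

# trapezoid quadrature weights for a uniform-ish grid
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

# --- parabolic inlet velocity mapping ----------------------------------------

#' Map a flow rate onto a non-circular inlet cross-section
#'
#' Distributes an instantaneous flow rate over an arbitrary planar inlet
#' section while keeping a parabolic profile shape: each sample point at
#' normalized centroid-to-boundary distance `rho = d / d_boundary` along its
#' ray receives velocity proportional to `1 - rho^2`, and the whole profile
#' is rescaled so the discrete surface integral reproduces the prescribed
#' flow exactly.
#'
#' @param inlet_section List with `points` (n x 2 matrix of sample
#'   coordinates, cm) and `boundary` (m x 2 matrix of polygon vertices,
#'   counter-clockwise). See [circular_section()].
#' @param Q_t Flow rate at this instant, mL/s.
#' @return List of class `inlet_map`: `velocity` (per point, cm/s), `weights`
#'   (per-point area weights, cm^2), `total_flow` (discrete integral, equals
#'   `Q_t`).
#' @export
map_inlet_velocity <- function(inlet_section, Q_t) {
  pts <- inlet_section$points
  bnd <- inlet_section$boundary
  A <- polygon_area(bnd)
  if (A <= 0) stop("degenerate (zero-area) inlet section")
  n <- nrow(pts)
  cen <- colMeans(bnd[-nrow(bnd), , drop = FALSE])
  if (!is.null(inlet_section$centroid)) cen <- inlet_section$centroid
  rho <- vapply(seq_len(n), function(i) {
    p <- pts[i, ]
    d <- sqrt(sum((p - cen)^2))
    if (d < 1e-12) return(0)
    dir <- (p - cen) / d
    dmax <- ray_boundary_distance(cen, dir, bnd)
    min(d / dmax, 1)
  }, numeric(1))
  shape <- 1 - rho^2
  w <- rep(A / n, n)                   # uniform-density sampling assumed
  tot <- sum(shape * w)
  vel <- if (Q_t == 0) rep(0, n) else shape * (Q_t / tot)
  structure(list(velocity = vel, weights = w, total_flow = sum(vel * w)),
            class = "inlet_map")
}

polygon_area <- function(b) {
  x <- b[, 1]; y <- b[, 2]
  n <- nrow(b)
  if (sqrt(sum((b[1, ] - b[n, ])^2)) > 1e-12) { x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1 }
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# distance from `origin` along unit `dir` to the polygon boundary
ray_boundary_distance <- function(origin, dir, b) {
  n <- nrow(b)
  if (sqrt(sum((b[1, ] - b[n, ])^2)) > 1e-12) b <- rbind(b, b[1, ])
  best <- Inf
  for (i in seq_len(nrow(b) - 1)) {
    p1 <- b[i, ]; p2 <- b[i + 1, ]
    e <- p2 - p1
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-14) next
    rhs <- p1 - origin
    tpar <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    upar <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
    if (tpar > 1e-12 && upar >= -1e-12 && upar <= 1 + 1e-12) best <- min(best, tpar)
  }
  if (!is.finite(best)) stop("ray does not hit the section boundary")
  best
}

#' Build simple inlet sections for the parabolic mapping
#'
#' `circular_section()` and `elliptical_section()` return uniform interior
#' sample grids plus a polygonal boundary, suitable for
#' [map_inlet_velocity()].
#'
#' @param radius Circle radius, cm.
#' @param a,b Ellipse semi-axes, cm.
#' @param n_boundary Polygon vertices on the boundary.
#' @param spacing Grid spacing of interior points, cm.
#' @return List with `points`, `boundary`, `centroid`.
#' @export
circular_section <- function(radius, n_boundary = 256L, spacing = radius / 24) {
  elliptical_section(radius, radius, n_boundary, spacing)
}

#' @rdname circular_section
#' @export
elliptical_section <- function(a, b, n_boundary = 256L, spacing = min(a, b) / 24) {
  th <- seq(0, 2 * pi, length.out = n_boundary + 1)[-(n_boundary + 1)]
  bnd <- cbind(a * cos(th), b * sin(th))
  g <- expand.grid(x = seq(-a, a, by = spacing), y = seq(-b, b, by = spacing))
  keep <- (g$x / a)^2 + (g$y / b)^2 < 1
  list(points = as.matrix(g[keep, , drop = FALSE]), boundary = bnd,
       centroid = c(0, 0))
}
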