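# The coupled wounded-plant model.
#
# Geometry reduction: the leaf pair is a 1-D axial xylem line x in [0, L]
# (x = 0 the wound at the tip of the wounded leaf, stem node at x = L/2,
# distant leaf tip at x = L). Each axial station carries a 1-D transverse
# tissue slab y in [0, W] (W = half vein spacing) with water-potential
# continuity at the vein, P_t(y = 0) = P_xyl(x, t) + pi_t, and symmetry
# (no flux) at mid-spacing y = W.
#
# Per unit vein length, with C_x = c_xyl a_xyl and K_x = kappa_xyl C_x:
#   C_x dP_xyl/dt = K_x d2P_xyl/dx2 - Q_t - Q_E + Q_stem + wound flux
#   Q_t   = 2 d_th k_t dP_t/dy|_{y=0}   (membrane draw, both sides of vein)
#   Q_E   = 2 E (2W)                    (both leaf surfaces, strip width 2W)
#   Q_stem= h_stem a_stem (0 - P_xyl)   (lumped stem water source, one cell)
# and at each station c_t dP_t/dt = k_t d2P_t/dy2.
#
# Time integration is fully implicit (backward Euler) with exact implicit
# xylem-tissue coupling via a Schur complement: the transverse solve's
# boundary flux is affine in the Dirichlet value, F = (2 k_t/dy)((1-a) V - b),
# with 'a' one scalar shared by all stations and 'b' one backsolve per
# station (vectorized multi-RHS Thomas). The axial solve then absorbs the
# (1-a) coefficient on its diagonal, so each global step is two tridiagonal
# solves and is discretely water-conserving to roundoff.

.geom_times <- function(t_first, t_end, n_times) {
  c(0, exp(seq(log(t_first), log(t_end), length.out = n_times)))
}

#' Pre-wound steady state of the plant
#'
#' Solves the steady axial xylem balance with the distributed transpiration
#' draw `2E(2W)` per unit vein length, the lumped stem source at `x = L/2`
#' conducting to 0 Pa gauge, and sealed leaf tips; the tissue sits in local
#' water-potential equilibrium, `P_t = P_xyl + pi_t`. Presets are calibrated
#' so the spatial mean xylem pressure equals the characteristic tension `P0`.
#'
#' @param s a `scenario`.
#' @param cfg a [solver_config()].
#' @return list of class `system_state`: `P_xyl` (axial vector \[Pa\]),
#'   `P_t` (`n_x x n_y` matrix \[Pa\]), meshes, `t = 0`.
#' @export
steady_state <- function(s, cfg = solver_config()) {
  nx <- cfg$n_cells_x
  mx <- mesh1d(s$L, nx)
  my <- mesh1d(half_spacing(s), cfg$n_cells_y)
  G <- s$h_stem * s$a_stem
  if (s$E > 0 && G <= 0) {
    stop("no steady state exists: transpiration E > 0 with zero stem conductance")
  }
  if (s$E == 0) {
    P <- rep(0, nx)
  } else {
    Kx <- s$kappa_xyl * s$c_xyl * s$a_xyl
    dx <- mx$dx
    QE <- 2 * s$E * s$vein_spacing          # mol m^-1 s^-1
    i_stem <- which.min(abs(mx$centers - s$L / 2))
    w <- Kx / dx
    dg <- rep(2 * w, nx); dg[c(1, nx)] <- w
    dg[i_stem] <- dg[i_stem] + G
    # cell balance: sum(face fluxes) + G (0 - P) - QE dx = 0
    # => (graph Laplacian + G e_stem) P = -QE dx
    P <- tridiag_solve(rep(-w, nx - 1), dg, rep(-w, nx - 1), rep(-QE * dx, nx))
  }
  structure(list(P_xyl = P,
                 P_t = matrix(P + s$pi_t, nx, cfg$n_cells_y),
                 mesh_x = mx, mesh_y = my, t = 0, scenario = s),
            class = "system_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the coupled wound response
#'
#' Time-integrates the coupled xylem-tissue system from the pre-wound state.
#' The wound cell holds `P_xyl = wound_pressure` while released water lasts
#' (sustained: forever; depleting: until the cumulative wound influx reaches
#' `reservoir_moles`, after which the wound seals to no-flux; the switch time
#' is recorded). Initial condition: the computed pre-wound steady state when
#' `E > 0` (or when no wound is present); uniform tension `P0` with tissue at
#' `P0 + pi_t` for nontranspiring (`E = 0`) wounded runs, matching the
#' published nontranspiring simulations.
#'
#' Two integration modes: `"full"` retains the xylem capacitive term and
#' resolves the fast transient on a geometric time grid starting near
#' `tau_xyl`; `"quasi_steady"` drops it (axial elliptic solve per step),
#' exploiting `tau_xyl << tau_t`.
#'
#' @param s a `scenario` (wound mode usually not `"none"`).
#' @param cfg a [solver_config()].
#' @param mode `"full"` or `"quasi_steady"`.
#' @return object of class `systemic_result`: `times`, `P_xyl`
#'   (`n_t x n_x`), `P_t` (`n_t x n_x x n_y` array), axial molar flow `J` at
#'   faces (`n_t x (n_x+1)`, \[mol s^-1\], positive away from the wound),
#'   `balance` data frame, `switch_time`, meshes, scenario.
#' @export
simulate_wound_response <- function(s, cfg = solver_config(),
                                    mode = c("full", "quasi_steady")) {
  mode <- match.arg(mode)
  ts <- characteristic_timescales(s)
  t_end <- cfg$t_end %||% (3 * ts[["tau_t"]])
  nx <- cfg$n_cells_x
  ny <- cfg$n_cells_y
  mx <- mesh1d(s$L, nx)
  my <- mesh1d(half_spacing(s), ny)
  dx <- mx$dx
  dy <- my$dx

  wound_on <- s$wound$mode != "none"
  # --- initial condition (see roxygen) ---
  if (!wound_on || s$E > 0) {
    st0 <- steady_state(s, cfg)
    P <- st0$P_xyl
    Pt <- t(st0$P_t)            # ny x nx, columns are axial stations
  } else {
    P <- rep(s$P0, nx)
    Pt <- matrix(s$P0 + s$pi_t, ny, nx)
  }

  # one grid for both modes (so full vs quasi-steady compare pointwise);
  # starts deep inside the fast xylem transient
  t_first <- min(ts[["tau_xyl"]] / 20, t_end / 1e6)
  times <- .geom_times(t_first, t_end, cfg$n_times)

  Cx <- s$c_xyl * s$a_xyl
  Kx <- s$kappa_xyl * Cx
  kt <- s$kappa_t * s$c_t
  G <- s$h_stem * s$a_stem
  QE <- 2 * s$E * s$vein_spacing
  i_stem <- which.min(abs(mx$centers - s$L / 2))
  Pw <- s$wound$wound_pressure
  reservoir <- if (identical(s$wound$mode, "depleting_reservoir"))
    s$wound$reservoir_moles else Inf
  wound_active <- wound_on
  cum_wound <- 0
  switch_time <- NA_real_

  wy <- kt / dy^2
  gy <- 2 * kt / dy              # F = gy/dy ... boundary flux coefficient
  n_t <- length(times)
  out_P <- matrix(NA_real_, n_t, nx)
  out_Pt <- array(NA_real_, c(n_t, nx, ny))
  out_J <- matrix(NA_real_, n_t, nx + 1)
  bal <- matrix(0, n_t, 6,
                dimnames = list(NULL, c("wound_influx", "stem_influx",
                                        "transpiration_efflux",
                                        "tissue_storage_rate",
                                        "xylem_storage_rate", "residual")))
  out_P[1, ] <- P
  out_Pt[1, , ] <- t(Pt)
  out_J[1, ] <- c(0, -Kx * diff(P) / dx, 0)

  for (k in 2:n_t) {
    dt_out <- times[k] - times[k - 1]
    dt <- dt_out / cfg$n_sub
    # transverse implicit bands for this dt (per volume, field P_t):
    #   (c_t/dt) Pt+ - k_t L Pt+ = (c_t/dt) Pt + g V
    dgy <- s$c_t / dt + c(3 * wy, rep(2 * wy, ny - 2), wy)
    loy <- rep(-wy, ny - 1)
    upy <- rep(-wy, ny - 1)
    gvec <- c(2 * wy, rep(0, ny - 1))
    a1 <- tridiag_solve(loy, dgy, upy, gvec)[1]
    beta <- 2 * s$d_th * (2 * kt / dy) * (1 - a1)   # per length per Pa

    for (j in seq_len(cfg$n_sub)) {
      rhs_t <- (s$c_t / dt) * Pt
      Bsol1 <- tridiag_solve(loy, dgy, upy, rhs_t)[1, ]   # b_i per station
      # axial implicit solve (extensive, mol/s per cell)
      cap <- if (mode == "full") Cx * dx / dt else 0
      w <- Kx / dx
      dg <- cap + c(w, rep(2 * w, nx - 2), w) + beta * dx
      dg[i_stem] <- dg[i_stem] + G
      if (wound_active) dg[1] <- dg[1] + 2 * w
      rhs <- cap * P -
        (beta * s$pi_t - 2 * s$d_th * (2 * kt / dy) * Bsol1) * dx -
        rep(QE * dx, nx)
      if (wound_active) rhs[1] <- rhs[1] + 2 * w * Pw
      Pn <- tridiag_solve(rep(-w, nx - 1), dg, rep(-w, nx - 1), rhs)
      # tissue update with the new Dirichlet values
      V <- Pn + s$pi_t
      Ptn <- tridiag_solve(loy, dgy, upy,
                           rhs_t + outer(gvec, V))
      Fmem <- (2 * kt / dy) * (V - Ptn[1, ])   # mol m^-2 s^-1 into tissue
      J_w <- if (wound_active) 2 * w * (Pw - Pn[1]) else 0
      cum_wound <- cum_wound + max(J_w, 0) * dt
      t_now <- times[k - 1] + j * dt
      if (wound_active && cum_wound >= reservoir) {
        wound_active <- FALSE
        switch_time <- t_now
      }
      P_prev <- P; Pt_prev <- Pt
      P <- Pn; Pt <- Ptn
      if (j == cfg$n_sub) {
        stem_in <- G * (0 - P[i_stem])
        transp <- QE * s$L
        xyl_store <- if (mode == "full") sum(Cx * dx * (P - P_prev) / dt) else 0
        tis_store <- sum(2 * s$d_th * dx * Fmem)
        resid <- J_w + stem_in - transp - xyl_store - tis_store
        bal[k, ] <- c(J_w, stem_in, transp, tis_store, xyl_store, resid)
      }
    }
    out_P[k, ] <- P
    out_Pt[k, , ] <- t(Pt)
    J_int <- -Kx * diff(P) / dx
    J_left <- if (wound_active) 2 * (Kx / dx) * (Pw - P[1]) else 0
    out_J[k, ] <- c(J_left, J_int, 0)
  }

  max_term <- pmax(abs(bal[, 1]), abs(bal[, 2]), abs(bal[, 3]),
                   abs(bal[, 4]), abs(bal[, 5]))
  # absolute floor: roundoff noise of the tissue-coupling cancellation for a
  # quiescent (no-flow) plant must not trip the relative check
  atol <- 1e5 * .Machine$double.eps *
    (2 * s$d_th * (2 * kt / dy)) * (abs(s$P0) + s$pi_t) * s$L
  ok <- abs(bal[, "residual"]) <= pmax(1e-6 * max_term, atol)
  if (!all(ok)) {
    stop(sprintf("water balance violated: max |residual|/max-term = %.3g",
                 max(abs(bal[, "residual"]) / pmax(max_term, 1e-300))))
  }
  if (!is.na(switch_time) && switch_time <= times[2]) {
    warning("depleting reservoir exhausted before the first output time")
  }
  structure(list(times = times, P_xyl = out_P, P_t = out_Pt, J = out_J,
                 balance = as.data.frame(cbind(time_s = times, bal)),
                 switch_time = switch_time, mesh_x = mx, mesh_y = my,
                 scenario = s, mode = mode, cfg = cfg),
            class = "systemic_result")
}

#' @export
print.systemic_result <- function(x, ...) {
  cat(sprintf(
    "<systemic_result:%s> %d times to %.4g s, mesh %d x %d, wound %s\n",
    x$mode, length(x$times), max(x$times), x$mesh_x$n_cells, x$mesh_y$n_cells,
    x$scenario$wound$mode))
  if (!is.na(x$switch_time)) {
    cat(sprintf("  reservoir exhausted at t = %.4g s\n", x$switch_time))
  }
  invisible(x)
}

#' Water balance audit of a systemic run
#'
#' Every flux and storage term is accumulated from the same discrete fluxes
#' the integrator used, so `residual = influxes - effluxes - storage` is a
#' true conservation audit (roundoff-level for a correct step).
#'
#' @param result a `systemic_result`.
#' @return data frame with per-time columns `wound_influx`, `stem_influx`,
#'   `transpiration_efflux`, `tissue_storage_rate`, `xylem_storage_rate`,
#'   `residual` \[mol s^-1\].
#' @export
water_balance <- function(result) {
  stopifnot(inherits(result, "systemic_result"))
  result$balance
}

#' Transverse tissue pressure history at one axial station
#'
#' @param result a `systemic_result`.
#' @param x_index axial cell index (default: station nearest L/4).
#' @return a [field_series()] on the transverse mesh.
#' @export
tissue_series <- function(result, x_index = NULL) {
  nx <- result$mesh_x$n_cells
  if (is.null(x_index)) x_index <- max(1L, round(nx / 4))
  field_series(result$mesh_y, result$times, result$P_t[, x_index, ],
               kind = "pressure")
}

#' Time for mid-spacing tissue pressure to reach a recovery fraction
#'
#' Recovery is measured at the mid-spacing cell (farthest from the vein)
#' relative to the full excursion from the initial value to the wounded
#' equilibrium `wound_pressure + pi_t`; the crossing time is interpolated
#' between outputs. Used to recover the `t ~ W^2` tissue scaling from full
#' simulations.
#'
#' @param result a `systemic_result`.
#' @param frac recovery fraction in (0, 1).
#' @param x_index axial station (default nearest L/4).
#' @export
tissue_recovery_time <- function(result, frac = 0.63, x_index = NULL) {
  stopifnot(frac > 0, frac < 1)
  s <- result$scenario
  nx <- result$mesh_x$n_cells
  if (is.null(x_index)) x_index <- max(1L, round(nx / 4))
  p <- result$P_t[, x_index, result$mesh_y$n_cells]
  target <- p[1] + frac * ((s$wound$wound_pressure + s$pi_t) - p[1])
  rel <- (p - p[1])
  goal <- target - p[1]
  idx <- which(rel >= goal)[1]
  if (is.na(idx)) return(NA_real_)
  if (idx == 1) return(0)
  t0 <- result$times[idx - 1]; t1 <- result$times[idx]
  r0 <- rel[idx - 1]; r1 <- rel[idx]
  t0 + (goal - r0) / (r1 - r0) * (t1 - t0)
}
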