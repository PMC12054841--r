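# Wound-induced leaf swelling: converts tissue pressure transients into
# volumetric strain and normalized leaf-thickness kinetics, including the
# vein-spacing dependence observed in wheat.

#' Standalone transverse tissue relaxation after full xylem equilibration
#'
#' Runs the tissue slab `y in [0, W]` with the vein boundary stepped at
#' `t = 0` from the pre-wound equilibrium `P0 + pi_t` to the post-wound value
#' `wound_pressure + pi_t` (justified by `tau_xyl` being far below the
#' experimental time resolution), sealed at mid-spacing. This is the
#' nontranspiring, sustained-wound idealization used for swelling kinetics.
#'
#' @param s a `scenario`.
#' @param vein_spacing override of `s$vein_spacing` \[m\] (optional).
#' @param times output times \[s\]; default geometric+0 grid to `6 tau_t`.
#' @param n_y transverse cells.
#' @param theta,n_sub time-scheme controls (Crank-Nicolson default here:
#'   these standalone runs are the package's accuracy workhorse).
#' @return a [field_series()] of tissue pressure on the transverse mesh.
#' @export
transverse_relaxation <- function(s, vein_spacing = NULL, times = NULL,
                                  n_y = 64, theta = 0.5, n_sub = 4) {
  W <- (vein_spacing %||% s$vein_spacing) / 2
  tau <- W^2 / s$kappa_t
  if (is.null(times)) {
    times <- c(0, tau * exp(seq(log(1e-3), log(6), length.out = 180)))
  }
  my <- mesh1d(W, n_y)
  solve_diffusion(my, s$P0 + s$pi_t, s$kappa_t,
                  bc_fixed(s$wound$wound_pressure + s$pi_t), bc_no_flux(),
                  times = times, theta = theta, n_sub = n_sub,
                  kind = "pressure")
}

#' Volumetric strain and normalized thickness from a tissue pressure series
#'
#' Linear, isotropic poroelastic strain: `eps(y, t) = Vw c_t (P_t - P_t(0))`,
#' i.e. the volume of water stored per unit tissue volume. The normalized
#' thickness `theta(t)` is the spatial mean strain relative to its
#' equilibrium value `Vw c_t (wound_pressure - P0)` (exact, rather than the
#' last sample, so `theta -> 1` holds asymptotically).
#'
#' @param pt_series a pressure [field_series()] on the transverse mesh (from
#'   [transverse_relaxation()] or [tissue_series()]).
#' @param s the `scenario` that produced it.
#' @return object of class `dilation_series`: `times`, `strain`
#'   (`n_t x n_y`), `theta`, `vein_spacing`, `kappa_t`, `eps_eq`.
#' @export
dilation_field <- function(pt_series, s) {
  stopifnot(inherits(pt_series, "field_series"), pt_series$kind == "pressure")
  dP <- sweep(pt_series$values, 2, pt_series$values[1, ])
  eps <- s$Vw * s$c_t * dP
  eps_eq <- s$Vw * s$c_t * (s$wound$wound_pressure - s$P0)
  if (abs(eps_eq) < 1e-15 || max(abs(eps)) < 1e-15 * max(1, abs(eps_eq))) {
    stop("zero total dilation: run appears unwounded (P0 = wound_pressure?)")
  }
  structure(list(times = pt_series$times, strain = eps,
                 theta = rowMeans(eps) / eps_eq,
                 vein_spacing = 2 * pt_series$mesh$length,
                 kappa_t = s$kappa_t, eps_eq = eps_eq,
                 mesh = pt_series$mesh),
            class = "dilation_series")
}

#' @export
print.dilation_series <- function(x, ...) {
  cat(sprintf(
    "<dilation_series> 2W = %.3g m, eq. strain %.3g, theta(end) = %.4f\n",
    x$vein_spacing, x$eps_eq, x$theta[length(x$theta)]))
  invisible(x)
}

#' Leaf-thickness kinetics across vein spacings
#'
#' For each spacing, runs the transverse relaxation on a time grid scaled to
#' that spacing's own `tau_t = W^2 / kappa_t` (the discrete problem is then
#' exactly self-similar, so curves collapse when time is rescaled by `W^2`)
#' and returns the normalized thickness curves. Smaller spacings reach any
#' fixed level earlier.
#'
#' @param s a `scenario` (sustained wound, nontranspiring idealization).
#' @param vein_spacings vector of `2W` values \[m\]; default the published
#'   wheat triplet 0.2, 0.3, 0.4 mm.
#' @param n_y,theta,n_sub passed to [transverse_relaxation()].
#' @param t_end_factor horizon in units of each spacing's `tau_t`.
#' @param n_times points on the shared dimensionless grid.
#' @return named list of `dilation_series` (names = spacing in meters).
#' @export
thickness_kinetics <- function(s, vein_spacings = c(2e-4, 3e-4, 4e-4),
                               n_y = 64, theta = 0.5, n_sub = 4,
                               t_end_factor = 6, n_times = 180) {
  sgrid <- c(0, exp(seq(log(1e-3), log(t_end_factor), length.out = n_times)))
  out <- lapply(vein_spacings, function(vs) {
    tau <- (vs / 2)^2 / s$kappa_t
    fs <- transverse_relaxation(s, vein_spacing = vs, times = sgrid * tau,
                                n_y = n_y, theta = theta, n_sub = n_sub)
    dilation_field(fs, s)
  })
  names(out) <- format(vein_spacings, digits = 6)
  out
}

#' Characteristic tissue relaxation time of a thickness curve
#'
#' Returns the relaxation time two ways: (i) the scaling value
#' `tau = W^2 / kappa_t` (the headline number compared against experiments)
#' and (ii) a least-squares fit of `theta(t) = 1 - exp(-t / tau)` over the
#' rise `theta in [0.05, 0.95]`. For `2W = 0.3 mm` and
#' `kappa_t = 1e-10 m^2 s^-1` the headline value is 225 s = 3.75 min.
#'
#' @param series a `dilation_series` sampled past 95% of its plateau.
#' @return list with `tau_scaling`, `tau_fit`, `headline` (= `tau_scaling`),
#'   all \[s\].
#' @export
fit_relaxation_time <- function(series) {
  stopifnot(inherits(series, "dilation_series"))
  th <- series$theta
  t <- series$times
  if (max(th) < 0.95) stop("theta(t) not sampled past 95% of its plateau")
  if (any(diff(th) < -1e-8 * max(abs(th)))) {
    stop("non-monotonic thickness curve: fit rejected")
  }
  W <- series$vein_spacing / 2
  tau_scaling <- W^2 / series$kappa_t
  keep <- th >= 0.05 & th <= 0.95
  tt <- t[keep]; yy <- th[keep]
  sse <- function(tau) sum((yy - (1 - exp(-tt / tau)))^2)
  opt <- stats::optimize(sse, interval = c(min(tt[tt > 0]) / 10,
                                           max(tt) * 10), tol = 1e-10)
  list(tau_scaling = tau_scaling, tau_fit = opt$minimum,
       headline = tau_scaling)
}
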