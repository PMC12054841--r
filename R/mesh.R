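#' Uniform cell-centered 1-D mesh
#'
#' All solvers in the package operate on uniform, cell-centered finite-volume
#' meshes. `x0` is the coordinate of the left boundary face; by package
#' convention `x = 0` is the wound site and all reported distances are
#' measured from it.
#'
#' @param length domain length \[m\], > 0.
#' @param n_cells number of cells, >= 8.
#' @param x0 coordinate of the left face \[m\].
#' @return object of class `mesh1d` with fields `length`, `n_cells`, `dx`,
#'   `centers`, `faces`, `x0`.
#' @export
mesh1d <- function(length, n_cells, x0 = 0) {
  stopifnot(is.numeric(length), length > 0, is.finite(length))
  n_cells <- as.integer(n_cells)
  if (n_cells < 8L) stop("mesh1d needs n_cells >= 8")
  dx <- length / n_cells
  structure(
    list(length = length, n_cells = n_cells, dx = dx,
         centers = x0 + (seq_len(n_cells) - 0.5) * dx,
         faces = x0 + (0:n_cells) * dx, x0 = x0),
    class = "mesh1d")
}

#' @export
print.mesh1d <- function(x, ...) {
  cat(sprintf("<mesh1d> %d cells, dx = %.4g m, [%.4g, %.4g] m\n",
              x$n_cells, x$dx, x$x0, x$x0 + x$length))
  invisible(x)
}

#' Boundary conditions for the 1-D solvers
#'
#' Three kinds are supported, entering the discrete equations through
#' ghost-cell fluxes:
#' * `bc_fixed(value)` — Dirichlet value imposed at the boundary face;
#' * `bc_no_flux()` — homogeneous Neumann (symmetry / sealed boundary);
#' * `bc_conductance(conductance, far_value)` — flux
#'   `g * (far_value - f_boundary)` in field-flux units (for a pressure field
#'   with conductivity `k = kappa * c`, a physical membrane conductance
#'   `h` \[mol m^-2 Pa^-1 s^-1\] maps to `g = h / c` \[m s^-1\]). Houses the
#'   stem water-source node.
#'
#' @param value boundary value (Pa or mol m^-3).
#' @param conductance exchange coefficient `g` >= 0 \[m s^-1\].
#' @param far_value far-field value the conductance couples to.
#' @return object of class `boundary_condition`.
#' @export
bc_fixed <- function(value) {
  stopifnot(is.finite(value))
  structure(list(kind = "fixed_value", value = value), class = "boundary_condition")
}

#' @rdname bc_fixed
#' @export
bc_no_flux <- function() {
  structure(list(kind = "no_flux"), class = "boundary_condition")
}

#' @rdname bc_fixed
#' @export
bc_conductance <- function(conductance, far_value) {
  stopifnot(is.finite(conductance), conductance >= 0, is.finite(far_value))
  structure(list(kind = "conductance", conductance = conductance,
                 far_value = far_value), class = "boundary_condition")
}

#' A scalar field sampled on a mesh at a sequence of times
#'
#' @param mesh a [mesh1d()].
#' @param times strictly increasing times \[s\], starting at 0 (the initial
#'   condition occupies the first row).
#' @param values `length(times) x n_cells` matrix.
#' @param kind one of `"pressure"`, `"concentration"`, `"strain"`.
#' @return object of class `field_series`.
#' @export
field_series <- function(mesh, times, values, kind = "pressure") {
  kind <- match.arg(kind, c("pressure", "concentration", "strain"))
  stopifnot(inherits(mesh, "mesh1d"))
  times <- as.numeric(times)
  if (times[1] != 0) stop("field_series times must start at 0 (initial condition)")
  if (any(diff(times) <= 0)) stop("field_series times must be strictly increasing")
  values <- as.matrix(values)
  if (nrow(values) != length(times) || ncol(values) != mesh$n_cells) {
    stop("field_series values must be n_times x n_cells")
  }
  if (any(!is.finite(values))) stop("field_series values must be finite")
  structure(list(mesh = mesh, times = times, values = values, kind = kind),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series:%s> %d times in [0, %.4g] s on %d cells\n",
              x$kind, length(x$times), max(x$times), x$mesh$n_cells))
  invisible(x)
}

#' Long-format data frame view of a field series
#'
#' Columns `time_s`, `position_m`, `value`, `field_kind` — the on-disk CSV
#' schema shared by all run artifacts.
#' @param x a [field_series()].
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.field_series <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    time_s = rep(x$times, each = x$mesh$n_cells),
    position_m = rep(x$mesh$centers, times = length(x$times)),
    value = as.vector(t(x$values)),
    field_kind = x$kind)
}
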