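#' Fluid presets for the colon-mimic media
#'
#' Constants for the two NaCMC test media: LOVIS (0.25% w/v) and HIVIS
#' (0.50% w/v) — power-law parameters, rest density, full-resolution SPH
#' particle mass, and the Newtonian-approximation viscosity used by the
#' solver.
#'
#' @param name `"LOVIS"` or `"HIVIS"`.
#' @return List with `K` (Pa s^n), `n`, `density` (kg m^-3),
#'   `particle_mass` (kg), `viscosity` (Pa s).
#' @export
fluid_preset <- function(name = c("LOVIS", "HIVIS")) {
  name <- match.arg(toupper(name), c("LOVIS", "HIVIS"))
  presets <- list(
    LOVIS = list(name = "LOVIS", K = 0.04, n = 0.87, density = 1017,
                 particle_mass = 1.324e-5, viscosity = 0.026),
    HIVIS = list(name = "HIVIS", K = 0.20, n = 0.74, density = 1020,
                 particle_mass = 1.328e-5, viscosity = 0.085))
  presets[[name]]
}

#' Power-law shear stress
#'
#' `tau = K * gamma_dot^n` (Pa) for a shear-thinning medium.
#'
#' @param K Consistency index (Pa s^n).
#' @param n Flow-behaviour index (0 < n <= 1).
#' @param gamma_dot Shear rate(s), s^-1.
#' @return Shear stress(es), Pa.
#' @export
power_law_stress <- function(K, n, gamma_dot) {
  stopifnot(K > 0, n > 0, n <= 1, all(gamma_dot >= 0))
  K * gamma_dot^n
}

#' Newtonian approximation of a power-law medium
#'
#' Fits a zero-intercept line to the power-law flow curve sampled uniformly
#' over the quasi-linear shear-rate range, returning its slope as the
#' effective Newtonian viscosity together with the R-squared of the linear
#' fit against the sampled curve. A free-intercept variant is available for
#' sensitivity checks.
#'
#' @param K,n Power-law parameters, or pass a preset via `preset`.
#' @param fit_range Shear-rate interval (s^-1) of the quasi-linear region.
#' @param n_points Sampling grid size over `fit_range`.
#' @param intercept Fit a free intercept instead of forcing the line through
#'   the origin.
#' @param preset Optional `"LOVIS"`/`"HIVIS"` shortcut.
#' @return A `rheology_fit` list: `viscosity` (Pa s), `r_squared`, `K`, `n`,
#'   `fit_range`, `intercept`.
#' @export
fit_effective_viscosity <- function(K = NULL, n = NULL, fit_range = c(0, 40),
                                    n_points = 401, intercept = FALSE,
                                    preset = NULL) {
  if (!is.null(preset)) {
    fp <- fluid_preset(preset)
    K <- fp$K; n <- fp$n
  }
  stopifnot(!is.null(K), !is.null(n), diff(fit_range) > 0, n_points >= 2)
  g <- seq(fit_range[1], fit_range[2], length.out = n_points)
  tau <- power_law_stress(K, n, g)
  if (intercept) {
    fit <- lm(tau ~ g)
    eta <- unname(coef(fit)[2])
    pred <- stats::fitted(fit)
  } else {
    eta <- sum(g * tau) / sum(g * g)   # zero-intercept least squares
    pred <- eta * g
  }
  ss_res <- sum((tau - pred)^2)
  ss_tot <- sum((tau - mean(tau))^2)
  structure(
    list(viscosity = eta, r_squared = 1 - ss_res / ss_tot,
         K = K, n = n, fit_range = fit_range, n_points = n_points,
         intercept = intercept),
    class = "rheology_fit")
}

#' Viscous-term coefficient from a target viscosity
#'
#' Inverts the effective-viscosity relation `nu = alpha * h_m * c0 / 10` of
#' the unconditional Monaghan viscous term:
#' `alpha = 10 (eta / rho0) / (h_m c0)`. The momentum smoothing length
#' enters because the term lives in the momentum equation.
#'
#' @param eta Dynamic viscosity (Pa s).
#' @param rho0 Rest density (kg m^-3).
#' @param h_m Momentum smoothing length (m).
#' @param c0 Artificial speed of sound (m s^-1).
#' @return Dimensionless `alpha`.
#' @export
alpha_from_viscosity <- function(eta, rho0, h_m = 9.42e-3, c0 = 0.1) {
  stopifnot(eta >= 0, rho0 > 0, h_m > 0, c0 > 0)
  10 * (eta / rho0) / (h_m * c0)
}

#' @export
print.rheology_fit <- function(x, ...) {
  cat(sprintf(
    "<rheology_fit> K = %.3g Pa s^n, n = %.3g: eta = %.1f mPa s (R^2 = %.4f) over %g-%g 1/s\n",
    x$K, x$n, 1000 * x$viscosity, x$r_squared, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Newtonian-approximation fit
#' @param x A `rheology_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fitted slope.
#' @export
tidy.rheology_fit <- function(x, ...) {
  tibble(term = "viscosity", estimate = x$viscosity, units = "Pa s")
}

#' One-row fit summary
#' @param x A `rheology_fit`.
#' @param ... Unused.
#' @export
glance.rheology_fit <- function(x, ...) {
  tibble(viscosity = x$viscosity, r_squared = x$r_squared,
         K = x$K, n = x$n,
         fit_lo = x$fit_range[1], fit_hi = x$fit_range[2],
         n_points = x$n_points, intercept = x$intercept)
}
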