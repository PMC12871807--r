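#' Guinier fit of a SAXS profile
#'
#' Linear regression of ln I on q^2 over the low-q Guinier window
#' q * Rg <= `qmax_rg`, iterated to self-consistency (the window depends on
#' the Rg it yields). The radius of gyration is
#' \eqn{R_g = \sqrt{-3\,\mathrm{slope}}}, with its standard deviation
#' propagated from the regression covariance. Scale-equivariant: rescaling
#' the intensities leaves Rg unchanged.
#'
#' @param q scattering vector, 1/Angstrom, ascending.
#' @param intensity scattered intensity I(q); must be positive inside the
#'   fit window.
#' @param qmax_rg dimensionless window limit (default 1.3, the standard
#'   globular-particle choice).
#' @return List with `rg`, `rg_sd` (Angstrom), `i0`, `n_used`, `window`
#'   (logical index of points used), `iterations`.
#' @examples
#' q <- seq(0.005, 0.2, by = 0.002)
#' I <- 100 * exp(-q^2 * 38^2 / 3)
#' guinier_fit(q, I)$rg
#' @export
guinier_fit <- function(q, intensity, qmax_rg = 1.3) {
  stopifnot(length(q) == length(intensity))
  if (is.unsorted(q)) stop("`q` must be ascending")
  window <- rep(TRUE, length(q))
  rg <- NA_real_
  for (iter in 1:20) {
    qs <- q[window]; Is <- intensity[window]
    if (sum(window) < 5)
      stop("fewer than 5 points in the Guinier window")
    if (any(Is <= 0))
      stop("non-positive intensities inside the Guinier window")
    fit <- lm(log(Is) ~ I(qs^2))
    slope <- coef(fit)[[2]]
    if (slope >= 0) stop("non-Guinier profile: ln I does not decay with q^2")
    rg_new <- sqrt(-3 * slope)
    new_window <- q * rg_new <= qmax_rg
    if (!any(new_window)) stop("empty Guinier window")
    converged <- isTRUE(all.equal(rg_new, rg, tolerance = 1e-10)) ||
      identical(new_window, window)
    rg <- rg_new
    if (converged) break
    window <- new_window
  }
  # exact synthetic profiles fit perfectly; the zero-residual warning from
  # the regression summary is expected there
  se_slope <- suppressWarnings(sqrt(vcov(fit)[2, 2]))
  list(rg = rg, rg_sd = 3 * se_slope / (2 * rg),
       i0 = exp(coef(fit)[[1]]), n_used = sum(window), window = window,
       iterations = iter)
}

#' Solution viscosity from a temperature calibration table
#'
#' Least-squares cubic (third-order polynomial) fit of viscosity against
#' temperature, evaluated at the query temperature. Queries outside the
#' tabulated range extrapolate with a warning.
#'
#' @param temperature tabulated temperatures (any consistent unit).
#' @param viscosity tabulated viscosities, cP.
#' @param query temperature(s) at which to evaluate, same unit.
#' @return Viscosity in cP at `query`.
#' @export
viscosity_from_calibration <- function(temperature, viscosity, query) {
  if (length(unique(temperature)) < 4)
    stop("at least 4 distinct temperatures are required for a cubic fit")
  if (any(query < min(temperature)) || any(query > max(temperature)))
    warning("query temperature outside the calibration range: extrapolating")
  fit <- lm(viscosity ~ poly(temperature, 3, raw = TRUE))
  unname(drop(cbind(1, query, query^2, query^3) %*% coef(fit)))
}

#' Rotational correlation time from the radius of gyration
#'
#' Stokes-Einstein rotational correlation time
#' \deqn{\tau_c = \frac{4\pi\,\eta_{visc}\,R^3}{3 k_B T}}
#' propagating the Rg uncertainty by Monte-Carlo: Rg is drawn from a
#' Gaussian truncated to positive values and mapped through the cubic
#' relation. With `rg_sd = 0` the result is the single deterministic value.
#' The radius defaults to Rg itself; `use_hydrodynamic_radius` rescales it
#' to Rh = Rg / 0.7746 (solid-sphere relation). The `/3` in the
#' denominator can be disabled for comparison with the alternative
#' rendering of the relation.
#'
#' @param rg_mean,rg_sd radius of gyration mean and sd, Angstrom.
#' @param viscosity_cP solution viscosity, centipoise.
#' @param temperature_K absolute temperature, K.
#' @param n_samples number of Monte-Carlo draws (ignored when `rg_sd` is 0).
#' @param seed integer seed.
#' @param denominator_3 keep the standard factor 3 in the denominator.
#' @param use_hydrodynamic_radius rescale Rg to a hydrodynamic radius.
#' @return Object of class `"tumbling_estimate"`: `tau_c_ns` (samples),
#'   `mean`, `sd`, plus the inputs.
#' @examples
#' tau_c_from_rg(37.85, 0, 1.099, 298.15)$mean  # about 61 ns
#' @export
tau_c_from_rg <- function(rg_mean, rg_sd = 0, viscosity_cP, temperature_K,
                          n_samples = 2000L, seed = 1L,
                          denominator_3 = TRUE,
                          use_hydrodynamic_radius = FALSE) {
  stopifnot(rg_mean > 0, rg_sd >= 0, viscosity_cP > 0, temperature_K > 0)
  if (rg_sd >= rg_mean / 3)
    warning("rg_sd >= rg_mean/3: positive truncation materially distorts ",
            "the tau_c distribution")
  kB <- 1.380649e-23
  visc <- viscosity_cP * 1e-3                      # cP -> Pa s
  scale <- if (use_hydrodynamic_radius) 1 / 0.7746 else 1
  denom <- (if (denominator_3) 3 else 1) * kB * temperature_K
  tau_of_rg <- function(rg_A) {
    r <- rg_A * scale * 1e-10                      # A -> m
    4 * pi * visc * r^3 / denom * 1e9              # s -> ns
  }
  if (rg_sd == 0) {
    samples <- tau_of_rg(rg_mean)
  } else {
    draws <- with_seed(seed, {
      x <- rnorm(n_samples, rg_mean, rg_sd)
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), rg_mean, rg_sd)
      x
    })
    samples <- tau_of_rg(draws)
  }
  structure(list(tau_c_ns = samples, mean = mean(samples),
                 sd = if (length(samples) > 1) sd(samples) else 0,
                 rg_mean = rg_mean, rg_sd = rg_sd,
                 viscosity_cP = viscosity_cP,
                 temperature_K = temperature_K,
                 denominator_3 = denominator_3,
                 use_hydrodynamic_radius = use_hydrodynamic_radius),
            class = "tumbling_estimate")
}

#' @export
print.tumbling_estimate <- function(x, ...) {
  cat(sprintf("<tumbling_estimate> tau_c = %.2f +/- %.2f ns (Rg %.2f A, %.3f cP, %.2f K)\n",
              x$mean, x$sd, x$rg_mean, x$viscosity_cP, x$temperature_K))
  invisible(x)
}

#' Convert between eta and the methyl-axis order parameter
#'
#' `eta_from_o2` evaluates the cross-correlated rate
#' \eqn{\eta = \frac{9}{10} [P_2(\cos\theta_{axis,HH})]^2 O^2_{axis}
#' (\mu_0/4\pi)^2 \gamma_H^4 \hbar^2 \tau_c / r_{HH}^6}
#' and `o2_from_eta_value` is its exact algebraic inverse; composing the
#' two is the identity for any positive constants.
#'
#' @param o2 methyl-axis order parameter(s).
#' @param eta cross-correlated relaxation rate(s), s^-1.
#' @param tau_c_ns rotational correlation time, ns.
#' @param constants a [physical_constants()] object.
#' @return `eta_from_o2`: eta in s^-1; `o2_from_eta_value`: O2axis.
#' @export
eta_from_o2 <- function(o2, tau_c_ns, constants = physical_constants()) {
  o2 * eta_per_o2(tau_c_ns * 1e-9, constants)
}

#' @rdname eta_from_o2
#' @export
o2_from_eta_value <- function(eta, tau_c_ns,
                              constants = physical_constants()) {
  eta / eta_per_o2(tau_c_ns * 1e-9, constants)
}

#' Methyl-axis order parameter distribution from an eta posterior
#'
#' Pairs random draws of eta (from a relaxation fit posterior) with random
#' draws of tau_c (from the Stokes-Einstein Monte-Carlo) and converts each
#' pair, propagating both uncertainties into the O2axis distribution.
#' Samples outside \[0, 1\] are counted and reported; they are clipped only
#' for motional-class assignment, never in the stored samples (downstream
#' reweighting targets need the real spread).
#'
#' @param eta_samples numeric vector of eta posterior draws (s^-1), or a
#'   `relax_fit` object from [fit_simultaneous_bayes()].
#' @param tumbling a [tau_c_from_rg()] result.
#' @param constants a [physical_constants()] object.
#' @param n_samples number of paired draws.
#' @param seed integer seed for the pairing.
#' @param residue_id,state labels carried into the result.
#' @return Object of class `"order_parameter_estimate"`: `o2` samples,
#'   `mean`, `sd`, `motional_class`, `frac_out_of_range`, `source = "NMR"`.
#' @export
o2_from_eta <- function(eta_samples, tumbling,
                        constants = physical_constants(),
                        n_samples = 2000L, seed = 1L,
                        residue_id = "peak", state = "state") {
  if (inherits(eta_samples, "relax_fit")) {
    residue_id <- eta_samples$peak_id
    eta_samples <- eta_samples$draws$eta
  }
  stopifnot(inherits(tumbling, "tumbling_estimate"),
            length(eta_samples) >= 1)
  tau <- tumbling$tau_c_ns
  n_excluded <- sum(tau <= 0)
  tau <- tau[tau > 0]
  resample <- function(x, n) {
    # sample() treats a length-1 numeric as 1:x; guard the degenerate case
    if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
  }
  draws <- with_seed(seed, {
    data.frame(eta = resample(eta_samples, n_samples),
               tau = resample(tau, n_samples))
  })
  o2 <- o2_from_eta_value(draws$eta, draws$tau, constants)
  frac_out <- mean(o2 < 0 | o2 > 1)
  if (frac_out > 0.05)
    warning(sprintf("%.1f%% of O2 samples fall outside [0, 1]",
                    100 * frac_out))
  m <- mean(o2)
  structure(list(residue_id = residue_id, state = state, source = "NMR",
                 o2 = o2, mean = m, sd = sd(o2),
                 motional_class = classify_motional_class(
                   min(max(m, 0), 1)),
                 frac_out_of_range = frac_out,
                 n_tau_excluded = n_excluded),
            class = "order_parameter_estimate")
}

#' @export
print.order_parameter_estimate <- function(x, ...) {
  cat(sprintf("<order_parameter_estimate> %s (%s, %s): O2 = %.3f +/- %.3f [%s]\n",
              x$residue_id, x$state, x$source, x$mean, x$sd,
              x$motional_class))
  invisible(x)
}

#' Motional class of a methyl order parameter
#'
#' Assigns the empirical motional classes of solution-state methyl
#' dynamics: the highly flexible J'-class (O2axis around 0.25) and J-class
#' (around 0.35) arising from multi-rotamer averaging, the alpha-class
#' (around 0.6, restricted rotameric jumps) and the omega-class (above 0.8,
#' libration within a single well). The conventional class centres are
#' turned into configurable boundaries.
#'
#' @param o2 order parameter value(s) in \[0, 1\].
#' @param boundaries upper edges of the J', J and alpha classes, ascending.
#' @return Character vector with levels `"J'"`, `"J"`, `"alpha"`,
#'   `"omega"`.
#' @examples
#' classify_motional_class(c(0.25, 0.35, 0.60, 0.85))
#' @export
classify_motional_class <- function(o2, boundaries = c(0.30, 0.50, 0.80)) {
  stopifnot(length(boundaries) == 3, !is.unsorted(boundaries))
  if (any(o2 < 0 | o2 > 1)) stop("`o2` must lie in [0, 1]")
  cls <- c("J'", "J", "alpha", "omega")
  cls[findInterval(o2, boundaries, left.open = TRUE) + 1L]
}

#' Write a per-residue order-parameter table
#'
#' TSV schema: `residue_id`, `state`, `source`, `o2_mean`, `o2_sd`,
#' `motional_class`, `n_samples`.
#'
#' @param estimates list of `order_parameter_estimate` objects.
#' @param path file path.
#' @export
write_o2_table <- function(estimates, path) {
  rows <- lapply(estimates, function(e)
    data.frame(residue_id = e$residue_id, state = e$state,
               source = e$source, o2_mean = e$mean, o2_sd = e$sd,
               motional_class = e$motional_class,
               n_samples = length(e$o2)))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
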