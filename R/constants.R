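#' Physical and geometric constants for the eta <-> O2axis conversion
#'
#' Bundles the constants entering the relation between the intra-methyl
#' cross-correlated relaxation rate eta and the methyl-axis order parameter
#' O2axis,
#' \deqn{\eta \approx \frac{9}{10}
#'   \left[\tfrac{1}{2}(3\cos^2\theta_{axis,HH}-1)\right]^2
#'   O^2_{axis}\, \frac{(\mu_0/4\pi)^2 \gamma_H^4 \hbar^2 \tau_c}{r_{HH}^6},}
#' and its algebraic inverse. The squared dipolar prefactor
#' \eqn{(\mu_0/4\pi)^2} is part of the standard proton--proton dipolar
#' coupling constant and is required for dimensional consistency (eta in
#' s^-1 with r_HH in metres and tau_c in seconds).
#'
#' Defaults are the standard methyl-relaxation values: r_HH = 1.813 A
#' (intra-methyl H--H distance), theta_axis_HH = 90 deg (angle between the
#' methyl symmetry axis and the H--H vector, giving a geometric factor of
#' 1/4 when squared), gamma_H = 2.6752218744e8 rad s^-1 T^-1.
#'
#' @param gamma_H proton gyromagnetic ratio, rad s^-1 T^-1.
#' @param hbar reduced Planck constant, J s.
#' @param r_HH intra-methyl H--H distance, Angstrom.
#' @param theta_axis_HH angle between methyl symmetry axis and H--H vector,
#'   degrees.
#' @param k_B Boltzmann constant, J K^-1.
#' @param mu0_over_4pi magnetic constant over 4 pi, T^2 m^3 J^-1 (1e-7 SI).
#' @return A named list of class `"physical_constants"`.
#' @examples
#' pc <- physical_constants()
#' pc$r_HH
#' @export
physical_constants <- function(gamma_H = 2.6752218744e8,
                               hbar = 1.054571817e-34,
                               r_HH = 1.813,
                               theta_axis_HH = 90,
                               k_B = 1.380649e-23,
                               mu0_over_4pi = 1e-7) {
  stopifnot(gamma_H > 0, hbar > 0, r_HH > 0, k_B > 0, mu0_over_4pi > 0)
  structure(list(gamma_H = gamma_H, hbar = hbar, r_HH = r_HH,
                 theta_axis_HH = theta_axis_HH, k_B = k_B,
                 mu0_over_4pi = mu0_over_4pi),
            class = "physical_constants")
}

# P2(cos theta) geometric factor, squared in the dipolar cross-correlation
axis_geometry_factor <- function(constants) {
  ct <- cos(constants$theta_axis_HH * pi / 180)
  0.5 * (3 * ct^2 - 1)
}

# eta (s^-1) per unit O2axis, for tau_c in seconds; r_HH converted A -> m
eta_per_o2 <- function(tau_c_s, constants) {
  g <- axis_geometry_factor(constants)
  r_m <- constants$r_HH * 1e-10
  (9 / 10) * g^2 * constants$mu0_over_4pi^2 * constants$gamma_H^4 *
    constants$hbar^2 * tau_c_s / r_m^6
}
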