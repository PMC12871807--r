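#' Closed-form 3Q/SQ intensity ratio
#'
#' Build-up of "forbidden" triple-quantum coherence relative to the decay of
#' "allowed" single-quantum coherence,
#' \deqn{\frac{I_{3Q}}{I_{SQ}} = \frac{3}{4}\,
#'   \frac{\eta \tanh(\sqrt{\eta^2+\delta^2}\,T)}
#'        {\sqrt{\eta^2+\delta^2} - \delta \tanh(\sqrt{\eta^2+\delta^2}\,T)}.}
#' The multi-exponential relaxation envelope and the shared amplitude cancel
#' in the ratio, so it depends on (eta, delta, T) only.
#'
#' @param eta intra-methyl cross-correlated relaxation rate, s^-1.
#' @param delta external-proton dipolar relaxation rate, s^-1.
#' @param delays relaxation delays T, seconds.
#' @return Numeric vector of ratios, one per delay.
#' @seealso [intensity_3q()], [intensity_sq()] for the separate curves.
#' @export
ratio_3q_sq <- function(eta, delta, delays) {
  s <- sqrt(eta^2 + delta^2)
  th <- tanh(s * delays)
  0.75 * eta * th / (s - delta * th)
}

#' 3Q and SQ intensity models with relaxation envelopes
#'
#' The ratio model reposed as two simultaneous curves sharing parameters:
#' \deqn{I_{3Q}(T) = 3\,\eta\tanh(\sqrt{\eta^2+\delta^2}T)\cdot A_0
#'   \sum_i f_i e^{-R_i T}}
#' \deqn{I_{SQ}(T) = 4\,(\sqrt{\eta^2+\delta^2} -
#'   \delta\tanh(\sqrt{\eta^2+\delta^2}T))\cdot A_0 \sum_i f_i e^{-R_i T}}
#' Dividing `intensity_3q` by `intensity_sq` recovers [ratio_3q_sq()]
#' exactly, for any relaxation envelope.
#'
#' @inheritParams ratio_3q_sq
#' @param amplitude shared amplitude A0 (arbitrary units).
#' @param rates relaxation rates R_i, s^-1 (length N >= 1).
#' @param fractions mixing fractions f_i (sum 1); default equal.
#' @return Numeric vector of intensities at `delays`.
#' @export
intensity_3q <- function(eta, delta, delays, amplitude = 1, rates = 0,
                         fractions = NULL) {
  env <- relaxation_envelope(delays, rates, fractions)
  s <- sqrt(eta^2 + delta^2)
  3 * eta * tanh(s * delays) * amplitude * env
}

#' @rdname intensity_3q
#' @export
intensity_sq <- function(eta, delta, delays, amplitude = 1, rates = 0,
                         fractions = NULL) {
  env <- relaxation_envelope(delays, rates, fractions)
  s <- sqrt(eta^2 + delta^2)
  4 * (s - delta * tanh(s * delays)) * amplitude * env
}

relaxation_envelope <- function(delays, rates, fractions = NULL) {
  if (length(rates) < 1L) stop("at least one relaxation rate is required")
  if (is.null(fractions)) fractions <- rep(1 / length(rates), length(rates))
  if (length(fractions) != length(rates))
    stop("`fractions` must match `rates` in length")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must sum to 1")
  drop(exp(-outer(delays, rates)) %*% fractions)
}

#' Specification of a synthetic 3Q/SQ decay-curve pair
#'
#' Ground-truth parameters for [simulate_decay_curves()]: the generator
#' evaluates the 3Q/SQ intensity models at these values and adds independent
#' homoscedastic Gaussian noise per coherence type, matching the likelihood
#' assumed by [fit_simultaneous_bayes()].
#'
#' @param eta,delta relaxation rates, s^-1 (delta >= 0).
#' @param amplitude shared amplitude A0.
#' @param rates relaxation rates R_i, s^-1.
#' @param fractions mixing fractions (default equal, sum 1).
#' @param delays strictly increasing positive delays, seconds.
#' @param noise_sd_sq,noise_sd_3q Gaussian noise standard deviations.
#' @param seed integer seed for reproducibility.
#' @param peak_id label carried to the generated curves.
#' @return Object of class `"decay_curve_spec"`.
#' @export
decay_curve_spec <- function(eta, delta, amplitude = 1, rates = 0,
                             fractions = NULL, delays,
                             noise_sd_sq = 0, noise_sd_3q = 0,
                             seed = 1L, peak_id = "peak1") {
  if (length(delays) < 1L || any(delays <= 0))
    stop("`delays` must be positive")
  if (is.unsorted(delays, strictly = TRUE))
    stop("`delays` must be strictly increasing")
  if (length(rates) < 1L) stop("`rates` must be non-empty")
  if (delta < 0) stop("`delta` must be >= 0")
  if (noise_sd_sq < 0 || noise_sd_3q < 0) stop("noise sds must be >= 0")
  if (is.null(fractions)) fractions <- rep(1 / length(rates), length(rates))
  if (abs(sum(fractions) - 1) > 1e-9) stop("`fractions` must sum to 1")
  structure(list(eta = eta, delta = delta, amplitude = amplitude,
                 rates = rates, fractions = fractions, delays = delays,
                 noise_sd_sq = noise_sd_sq, noise_sd_3q = noise_sd_3q,
                 seed = as.integer(seed), peak_id = peak_id),
            class = "decay_curve_spec")
}

#' Construct a decay curve
#'
#' One peak's intensity-vs-delay series for a single coherence type.
#'
#' @param peak_id peak label.
#' @param coherence `"SQ"` or `"3Q"`.
#' @param delays strictly increasing positive delays, seconds.
#' @param intensities intensities, arbitrary units.
#' @return Object of class `"decay_curve"`.
#' @export
decay_curve <- function(peak_id, coherence, delays, intensities) {
  coherence <- match.arg(coherence, c("SQ", "3Q"))
  if (any(delays <= 0) || is.unsorted(delays, strictly = TRUE))
    stop("`delays` must be positive and strictly increasing")
  if (length(intensities) != length(delays))
    stop("`intensities` must match `delays` in length")
  structure(list(peak_id = peak_id, coherence = coherence,
                 delays = as.numeric(delays),
                 intensities = as.numeric(intensities)),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %s %s, %d delays [%g, %g] s\n",
              x$peak_id, x$coherence, length(x$delays),
              min(x$delays), max(x$delays)))
  invisible(x)
}

#' Simulate an interleaved 3Q/SQ decay-curve pair
#'
#' Noiseless means follow the 3Q and SQ intensity models exactly; Gaussian
#' noise of the specified standard deviation is then added independently per
#' point. Reproducible given `spec$seed`.
#'
#' @param spec a [decay_curve_spec()].
#' @return List with elements `sq` and `tq` ([decay_curve()] objects) and
#'   `truth` (the generating parameters).
#' @examples
#' spec <- decay_curve_spec(eta = 30, delta = 5, rates = c(40, 120),
#'                          delays = seq(0.4, 10, length.out = 7) * 1e-3,
#'                          noise_sd_sq = 0.02, noise_sd_3q = 0.02)
#' curves <- simulate_decay_curves(spec)
#' @export
simulate_decay_curves <- function(spec) {
  stopifnot(inherits(spec, "decay_curve_spec"))
  mu_3q <- intensity_3q(spec$eta, spec$delta, spec$delays, spec$amplitude,
                        spec$rates, spec$fractions)
  mu_sq <- intensity_sq(spec$eta, spec$delta, spec$delays, spec$amplitude,
                        spec$rates, spec$fractions)
  n <- length(spec$delays)
  noise <- with_seed(spec$seed, {
    list(sq = rnorm(n, 0, spec$noise_sd_sq),
         tq = rnorm(n, 0, spec$noise_sd_3q))
  })
  list(sq = decay_curve(spec$peak_id, "SQ", spec$delays, mu_sq + noise$sq),
       tq = decay_curve(spec$peak_id, "3Q", spec$delays, mu_3q + noise$tq),
       truth = spec)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
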