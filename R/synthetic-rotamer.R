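#' Methyl-axis unit vector from the local spherical parameterization
#'
#' Maps the fixed polar bond angle theta (the Cg-Sd / Sd-Ce angle) and the
#' azimuthal chi dihedral to a unit vector
#' \deqn{\hat\mu = (\sin(\pi-\theta)\cos\phi,\ \sin(\pi-\theta)\sin\phi,\
#'   \cos(\pi-\theta)),}
#' with phi the chi dihedral in degrees mapped directly to the azimuth.
#'
#' @param theta_bond polar bond angle, degrees.
#' @param chi azimuthal dihedral angle(s), degrees.
#' @return n x 3 matrix of unit vectors (columns x, y, z).
#' @export
axis_from_angles <- function(theta_bond, chi) {
  pt <- pi - theta_bond * pi / 180
  phi <- chi * pi / 180
  cbind(x = sin(pt) * cos(phi), y = sin(pt) * sin(phi),
        z = rep(cos(pt), length(phi)))
}

#' Specification of a rotamer-jump trajectory
#'
#' Defines a Markov jump process among chi-dihedral wells (e.g. the
#' trans/gauche rotamers of methionine chi3) with Gaussian intra-well
#' libration, plus the fixed polar bond angle that maps chi to the
#' methyl-axis unit vector. The stationary well populations determine the
#' axis order parameter and the binned chi entropy analytically, so
#' simulated trajectories come with exact ground truth
#' ([analytic_o2_jump()], [analytic_chi_entropy()]).
#'
#' @param well_angles chi well centres, degrees in (-180, 180].
#' @param populations stationary probabilities, same length, sum 1.
#' @param exchange_prob per-frame probability of attempting a jump, in
#'   \[0, 1\].
#' @param libration_sd intra-well Gaussian width, degrees (>= 0).
#' @param theta_bond fixed polar bond angle, degrees.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return Object of class `"rotamer_jump_spec"`.
#' @examples
#' spec <- rotamer_jump_spec(well_angles = c(60, 180, -60),
#'                           populations = rep(1, 3) / 3,
#'                           theta_bond = 109.47, n_frames = 1000)
#' analytic_o2_jump(spec)  # 1/9 for this geometry
#' @export
rotamer_jump_spec <- function(well_angles, populations = NULL,
                              exchange_prob = 0.2, libration_sd = 0,
                              theta_bond = 109.47, n_frames, seed = 1L) {
  k <- length(well_angles)
  if (k < 1L) stop("at least one well is required")
  if (is.null(populations)) populations <- rep(1 / k, k)
  if (length(populations) != k)
    stop("`populations` must match `well_angles` in length")
  if (any(populations < 0) || abs(sum(populations) - 1) > 1e-12)
    stop("`populations` must be non-negative and sum to 1")
  if (exchange_prob < 0 || exchange_prob > 1)
    stopifnot("`exchange_prob` must be in [0, 1]" = FALSE)
  if (libration_sd < 0) stop("`libration_sd` must be >= 0")
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  if (k > 1L && libration_sd > 0) {
    gaps <- abs(wrap_angle(outer(well_angles, well_angles, "-")))
    min_gap <- min(gaps[upper.tri(gaps)])
    if (min_gap < 3 * libration_sd)
      warning("wells closer than 3 * libration_sd: libration may mix wells")
  }
  structure(list(well_angles = wrap_angle(well_angles),
                 populations = populations,
                 exchange_prob = exchange_prob,
                 libration_sd = libration_sd, theta_bond = theta_bond,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "rotamer_jump_spec")
}

# wrap degrees into (-180, 180]
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y[y <= -180] <- y[y <= -180] + 360  # guard numerical -180
  y
}

#' Simulate a rotamer-jump bond-vector / chi-angle trajectory
#'
#' Frames follow a Metropolis Markov chain among the wells (propose a
#' uniformly random other well with probability `exchange_prob`, accept by
#' population ratio), whose stationary law equals `spec$populations`.
#' Gaussian libration noise is added to the well centre and wrapped on the
#' circle; the methyl-axis unit vector is built from
#' (`theta_bond`, chi) via [axis_from_angles()].
#'
#' @param spec a [rotamer_jump_spec()].
#' @return List with `chi` (degrees, length n_frames), `well` (well index
#'   per frame), and `vectors` (n_frames x 3 unit vectors).
#' @export
simulate_rotamer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "rotamer_jump_spec"))
  k <- length(spec$well_angles)
  n <- spec$n_frames
  well <- with_seed(spec$seed, {
    s <- integer(n)
    s[1] <- sample.int(k, 1L, prob = spec$populations)
    if (k > 1L && n > 1L) {
      attempt <- runif(n) < spec$exchange_prob
      prop_u <- sample.int(k - 1L, n, replace = TRUE)
      acc_u <- runif(n)
      p <- spec$populations
      for (t in 2:n) {
        cur <- s[t - 1L]
        s[t] <- cur
        if (attempt[t]) {
          j <- prop_u[t]
          if (j >= cur) j <- j + 1L
          ratio <- if (p[cur] > 0) p[j] / p[cur] else Inf
          if (acc_u[t] < ratio) s[t] <- j
        }
      }
    } else if (n > 1L) s[2:n] <- s[1]
    s
  })
  chi <- spec$well_angles[well]
  if (spec$libration_sd > 0) {
    noise <- with_seed(spec$seed + 1000003L,
                       rnorm(n, 0, spec$libration_sd))
    chi <- wrap_angle(chi + noise)
  }
  list(chi = chi, well = well,
       vectors = axis_from_angles(spec$theta_bond, chi))
}

#' Analytic methyl-axis order parameter of a rotamer-jump model
#'
#' Evaluates the second-rank tensor expansion exactly over the stationary
#' mixture of wells with Gaussian libration, using the wrapped-normal
#' circular moments \eqn{E[e^{in\phi}] = e^{in\phi_0 - n^2\sigma^2/2}}.
#' No trajectory sampling is involved, so this serves as an independent
#' oracle for [o2_tensor()] on simulated trajectories.
#'
#' @param spec a [rotamer_jump_spec()]; `n_frames`/`seed` are ignored.
#' @param populations optional override of the stationary populations
#'   (e.g. a reweighting target over the same wells).
#' @return Scalar O2axis in \[0, 1\].
#' @export
analytic_o2_jump <- function(spec, populations = NULL) {
  stopifnot(inherits(spec, "rotamer_jump_spec"))
  p <- if (is.null(populations)) spec$populations else populations
  if (length(p) != length(spec$well_angles) ||
      abs(sum(p) - 1) > 1e-9 || any(p < 0))
    stop("invalid `populations` override")
  pt <- pi - spec$theta_bond * pi / 180
  a <- sin(pt); cz <- cos(pt)
  phi0 <- spec$well_angles * pi / 180
  s <- spec$libration_sd * pi / 180
  e1 <- exp(-s^2 / 2); e2 <- exp(-2 * s^2)
  # per-well second moments of mu, averaged over libration
  m_xx <- sum(p * a^2 * (1 + cos(2 * phi0) * e2) / 2)
  m_yy <- sum(p * a^2 * (1 - cos(2 * phi0) * e2) / 2)
  m_zz <- cz^2
  m_xy <- sum(p * a^2 * sin(2 * phi0) * e2 / 2)
  m_xz <- sum(p * a * cz * cos(phi0) * e1)
  m_yz <- sum(p * a * cz * sin(phi0) * e1)
  1.5 * (m_xx^2 + m_yy^2 + m_zz^2 +
           2 * (m_xy^2 + m_xz^2 + m_yz^2)) - 0.5
}

#' Analytic binned chi distribution and entropy of a rotamer-jump model
#'
#' Exact probability mass per 10-degree (by default) chi bin under the
#' stationary wrapped-Gaussian mixture, and the corresponding Gibbs-Shannon
#' entropy. Used as the ground-truth oracle for the histogram/entropy stage.
#'
#' @inheritParams analytic_o2_jump
#' @param bin_width bin width, degrees; must divide 360.
#' @param offset shift of the bin edges, degrees.
#' @return `analytic_chi_bin_probs`: numeric vector of bin masses (sum 1),
#'   named by bin centre; `analytic_chi_entropy`: scalar entropy (nats).
#' @export
analytic_chi_bin_probs <- function(spec, populations = NULL,
                                   bin_width = 10, offset = 0) {
  stopifnot(inherits(spec, "rotamer_jump_spec"))
  p <- if (is.null(populations)) spec$populations else populations
  edges <- seq(-180, 180, by = bin_width) + offset
  nb <- length(edges) - 1L
  mass <- numeric(nb)
  s <- spec$libration_sd
  for (i in seq_along(p)) {
    mu <- spec$well_angles[i]
    if (s == 0) {
      # point mass: right-closed bins (lo, hi]
      x <- wrap_angle(mu - offset) + offset
      k <- findInterval(x, edges, left.open = TRUE, rightmost.closed = TRUE)
      k <- min(max(k, 1L), nb)
      mass[k] <- mass[k] + p[i]
    } else {
      for (m in -3:3) {
        mass <- mass + p[i] *
          (pnorm(edges[-1], mu + 360 * m, s) -
             pnorm(edges[-length(edges)], mu + 360 * m, s))
      }
    }
  }
  names(mass) <- (edges[-length(edges)] + edges[-1]) / 2
  mass / sum(mass)
}

#' @rdname analytic_chi_bin_probs
#' @export
analytic_chi_entropy <- function(spec, populations = NULL,
                                 bin_width = 10, offset = 0) {
  pk <- analytic_chi_bin_probs(spec, populations, bin_width, offset)
  pk <- pk[pk > 0]
  -sum(pk * log(pk))
}

#' Simulate a multi-residue ensemble with known reweighting targets
#'
#' Generates `n_residues` independent rotamer-jump trajectories under the
#' prior populations, bundles them into a [trajectory_ensemble()] with
#' uniform frame weights, and returns the analytic order parameters under
#' the *target* populations. Reweighting the uniform-weight ensemble to
#' these targets should recover the target populations, making this the
#' standard recovery fixture for [optimize_weights()].
#'
#' @param spec_prior a [rotamer_jump_spec()] defining wells, libration,
#'   geometry, frame count, and the prior populations.
#' @param populations_target target stationary probabilities over the same
#'   wells; must be absolutely continuous w.r.t. the prior (no mass where
#'   the prior has none).
#' @param n_residues number of residues (independent trajectories).
#' @param seed integer seed; residue r uses `seed + r` internally.
#' @param target_sd reported uncertainty attached to each target O2.
#' @return List with `ensemble` (a [trajectory_ensemble()]), `targets`
#'   (data.frame residue_id, o2_mean, o2_sd), `populations_target`, and
#'   `spec_prior`.
#' @export
simulate_weighted_ensemble <- function(spec_prior, populations_target,
                                       n_residues = 1L, seed = 1L,
                                       target_sd = 0.02) {
  stopifnot(inherits(spec_prior, "rotamer_jump_spec"), n_residues >= 1)
  if (length(populations_target) != length(spec_prior$well_angles))
    stop("target populations must cover the same wells as the prior")
  if (any(populations_target < 0) ||
      abs(sum(populations_target) - 1) > 1e-9)
    stop("invalid target populations")
  if (any(populations_target > 0 & spec_prior$populations == 0))
    stop("target has mass where the prior has none: unreachable by reweighting")
  ids <- sprintf("R%03d", seq_len(n_residues))
  vectors <- vector("list", n_residues); names(vectors) <- ids
  chis <- vector("list", n_residues); names(chis) <- ids
  wells <- vector("list", n_residues); names(wells) <- ids
  for (r in seq_len(n_residues)) {
    sp <- spec_prior
    sp$seed <- as.integer(seed + r)
    traj <- simulate_rotamer_trajectory(sp)
    vectors[[r]] <- traj$vectors
    chis[[r]] <- matrix(traj$chi, ncol = 1,
                        dimnames = list(NULL, "chi3"))
    wells[[r]] <- traj$well
  }
  o2_target <- analytic_o2_jump(spec_prior, populations_target)
  targets <- data.frame(residue_id = ids, o2_mean = o2_target,
                        o2_sd = target_sd, stringsAsFactors = FALSE)
  ens <- trajectory_ensemble(vectors = vectors, chi = chis,
                             wells = wells)
  list(ensemble = ens, targets = targets,
       populations_target = populations_target, spec_prior = spec_prior)
}
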