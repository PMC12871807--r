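# shared fixtures and small oracles used across test files

# standard 7-delay grid of the round-trip study (seconds)
study_delays <- function() seq(0.4e-3, 10e-3, length.out = 7)

# decay-curve pair at the study conditions; noise quoted as a fraction of
# each curve's noiseless maximum
make_decay_pair <- function(eta = 30, delta = 5, rates = c(40, 120),
                            noise_frac = 0, seed = 1,
                            delays = study_delays()) {
  mu_sq <- intensity_sq(eta, delta, delays, 1, rates)
  mu_3q <- intensity_3q(eta, delta, delays, 1, rates)
  spec <- decay_curve_spec(eta, delta, 1, rates, NULL, delays,
                           noise_sd_sq = noise_frac * max(abs(mu_sq)),
                           noise_sd_3q = noise_frac * max(abs(mu_3q)),
                           seed = seed)
  simulate_decay_curves(spec)
}

# canonical 3-site methionine chi3 jump spec
met_jump_spec <- function(n_frames, populations = rep(1, 3) / 3,
                          libration_sd = 0, seed = 1) {
  rotamer_jump_spec(well_angles = c(60, 180, -60),
                    populations = populations,
                    libration_sd = libration_sd,
                    theta_bond = 109.47, n_frames = n_frames, seed = seed)
}

# solid-sphere SAXS form factor, the classical closed form
sphere_form_factor <- function(q, radius, i0 = 1) {
  x <- q * radius
  i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# weighted well populations of one residue of a jump-model ensemble
recovered_populations <- function(ensemble, weights, residue_index,
                                  n_wells = 3) {
  wl <- ensemble$wells[[residue_index]]
  vapply(seq_len(n_wells), function(k) sum(weights[wl == k]), numeric(1))
}

# smallest max-abs population error over all relabelings of the wells
# (the order parameter is invariant under these for equidistant wells)
pop_error_mod_symmetry <- function(pops, target) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  min(vapply(perms, function(pm) max(abs(pops - target[pm])), numeric(1)))
}

# memoized heavy recovery fixture shared by the reweighting/entropy
# acceptance blocks (computed once per test run)
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_recovery <- function() {
  if (!is.null(.acceptance_cache$recovery)) return(.acceptance_cache$recovery)
  spec <- met_jump_spec(n_frames = 20000, libration_sd = 10, seed = 2)
  fixture <- simulate_weighted_ensemble(spec, c(0.6, 0.2, 0.2),
                                        n_residues = 10, seed = 11)
  lcurve <- l_curve_scan(fixture$ensemble, fixture$targets,
                         10^seq(-2, 4, length.out = 13), max_iter = 3000)
  .acceptance_cache$recovery <- list(spec = spec, fixture = fixture,
                                     lcurve = lcurve)
  .acceptance_cache$recovery
}
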