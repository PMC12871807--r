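test_that("residue eligibility implements the chi-angle rules", {
  elig <- eligible_residues(c("MET", "GLY", "LYS", "ARG", "ALA", "SER",
                              "LEU"))
  expect_equal(elig$included,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(elig$n_chi[elig$resname == "MET"], 3)
  expect_match(elig$reason[elig$resname == "GLY"], "no chi")
  expect_match(elig$reason[elig$resname == "LYS"], "more than 3")
  expect_warning(eligible_residues("XYZ"), "unknown")
})

test_that("weighted histograms place mass by bin and weight", {
  h <- weighted_dihedral_histogram(rep(55, 20))
  expect_equal(unname(h$probs[names(h$probs) == "55"]), 1)
  expect_equal(sum(h$probs > 0), 1L)
  # weights propagate directly
  h2 <- weighted_dihedral_histogram(c(55, -120), weights = c(0.6, 0.4))
  expect_equal(sort(h2$probs[h2$probs > 0], decreasing = TRUE),
               c(0.6, 0.4), ignore_attr = TRUE)
  # uniform angles approach 1/36 per bin
  set.seed(1)
  h3 <- weighted_dihedral_histogram(runif(2e5, -180, 180))
  expect_lt(max(abs(h3$probs - 1 / 36)), 0.005)
  # non-finite frames are dropped and counted
  h4 <- weighted_dihedral_histogram(c(10, NA, 20), rep(1 / 3, 3))
  expect_equal(h4$n_dropped, 1L)
  expect_equal(sum(h4$probs), 1, tolerance = 1e-12)
})

test_that("residue entropy reproduces closed forms", {
  single <- weighted_dihedral_histogram(rep(55, 10))
  expect_equal(residue_entropy(list(single)), 0, tolerance = 1e-12)
  # uniform over all 36 bins: ln 36
  centres <- seq(-175, 175, by = 10)
  uniform <- weighted_dihedral_histogram(centres,
                                         weights = rep(1 / 36, 36))
  expect_equal(residue_entropy(list(uniform)), log(36), tolerance = 1e-12)
  # three chi angles each split over three equal bins: ln 3
  tri <- weighted_dihedral_histogram(c(60, 180, -60), rep(1 / 3, 3))
  expect_equal(residue_entropy(list(tri, tri, tri), n_chi = 3), log(3),
               tolerance = 1e-12)
})

test_that("entropy never increases when mass concentrates", {
  base <- c(0.25, 0.25, 0.25, 0.25)
  angles <- c(-175, -60, 60, 175)
  h_base <- weighted_dihedral_histogram(angles, base)
  for (lambda in c(0.2, 0.5, 0.9)) {
    # shift mass toward a point mass on the first bin
    w <- (1 - lambda) * base + lambda * c(1, 0, 0, 0)
    h <- weighted_dihedral_histogram(angles, w)
    expect_lte(residue_entropy(list(h)),
               residue_entropy(list(h_base)) + 1e-12)
  }
})

test_that("entropy is invariant under origin shifts by whole bins", {
  set.seed(2)
  angles <- c(rnorm(500, 60, 8), rnorm(300, 180, 8), rnorm(200, -60, 8))
  angles <- ((angles + 180) %% 360) - 180
  s0 <- residue_entropy(list(weighted_dihedral_histogram(angles)))
  s1 <- residue_entropy(list(weighted_dihedral_histogram(angles + 30)))
  expect_equal(s1, s0, tolerance = 1e-12)
})

test_that("uniform-weight entropy equals the unweighted histogram entropy", {
  set.seed(3)
  angles <- runif(1000, -180, 180)
  h_w <- weighted_dihedral_histogram(angles, rep(1 / 1000, 1000))
  h_u <- weighted_dihedral_histogram(angles)
  expect_equal(residue_entropy(list(h_w)), residue_entropy(list(h_u)),
               tolerance = 1e-12)
})

test_that("build-up curves converge to the generating entropy", {
  spec <- met_jump_spec(1e4, populations = c(0.6, 0.2, 0.2),
                        libration_sd = 10, seed = 4)
  traj <- simulate_rotamer_trajectory(spec)
  bu <- entropy_buildup(traj$chi)
  expect_lt(abs(tail(bu$s_sc, 1) - analytic_chi_entropy(spec)), 0.05)
  # final checkpoint equals the full-set entropy exactly
  full <- residue_entropy(list(weighted_dihedral_histogram(traj$chi)))
  expect_equal(tail(bu$s_sc, 1), full, tolerance = 1e-12)
  # single-bin data: flat at zero
  bu0 <- entropy_buildup(rep(42, 500), checkpoints = c(10, 100, 500))
  expect_equal(bu0$s_sc, rep(0, 3))
})

test_that("entropy profiles apply eligibility and weighting", {
  fix <- simulate_weighted_ensemble(
    met_jump_spec(500, libration_sd = 10, seed = 5),
    c(0.6, 0.2, 0.2), n_residues = 3, seed = 6)
  ens <- fix$ensemble
  ens$residue_names[] <- c("MET", "GLY", "MET")
  prof <- entropy_profile(ens, state = "Apo")
  expect_equal(nrow(prof$residues), 2L)
  expect_equal(prof$excluded[[ens$residues[2]]], "no chi angle")
  expect_equal(prof$total, sum(prof$residues$s_sc))
  # concentrating weights lowers the profile entropy
  w <- rep(1e-6, 500); w[1:10] <- 1
  prof_conc <- entropy_profile(ens, weights = w, state = "conc")
  expect_true(all(prof_conc$residues$s_sc < prof$residues$s_sc))
  expect_true(all(prof_conc$residues$low_confidence))
})

test_that("entropy differences have the right sign and bookkeeping", {
  fix <- simulate_weighted_ensemble(
    met_jump_spec(2000, libration_sd = 10, seed = 7),
    c(0.9, 0.05, 0.05), n_residues = 2, seed = 8)
  prior <- entropy_profile(fix$ensemble, state = "prior")
  expect_equal(delta_entropy(prior, prior)$table$delta_s, c(0, 0))
  res <- optimize_weights(fix$ensemble, fix$targets, theta = 0.01)
  rew <- entropy_profile(fix$ensemble, weights = res$weights,
                         state = "reweighted")
  dS <- delta_entropy(prior, rew)
  # reweighting toward a concentrated rotamer mixture loses entropy
  expect_true(all(dS$table$delta_s < 0))
  expect_equal(dS$delta_total, sum(dS$table$delta_s))
  # one-residue uniform-vs-point closed form
  u <- structure(list(residues = data.frame(residue_id = "R1",
                                            resname = "SER", n_chi = 1,
                                            s_sc = log(36),
                                            low_confidence = FALSE),
                      total = log(36), state = "b", excluded = list()),
                 class = "entropy_profile")
  z <- u; z$residues$s_sc <- 0; z$total <- 0; z$state <- "a"
  expect_equal(delta_entropy(z, u)$table$delta_s, log(36),
               tolerance = 1e-12)
})

test_that("joint-mode entropy matches marginals for independent dihedrals", {
  # all mass in one joint bin: zero by either route
  angles <- cbind(chi1 = rep(55, 50), chi2 = rep(-120, 50))
  expect_equal(residue_entropy(angles = angles, joint = TRUE), 0,
               tolerance = 1e-12)
  # independent uniform dihedrals: joint entropy / n_chi = mean marginal
  set.seed(9)
  a2 <- cbind(chi1 = runif(5e4, -180, 180), chi2 = runif(5e4, -180, 180))
  joint <- residue_entropy(angles = a2, joint = TRUE)
  marg <- residue_entropy(list(
    weighted_dihedral_histogram(a2[, 1]),
    weighted_dihedral_histogram(a2[, 2])), n_chi = 2)
  expect_lt(abs(joint - marg), 0.02)
})
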