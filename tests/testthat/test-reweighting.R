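small_fixture <- function(n_frames = 400, n_residues = 3, seed = 1,
                          target = c(0.6, 0.2, 0.2), libration_sd = 10) {
  spec <- met_jump_spec(n_frames, libration_sd = libration_sd, seed = seed)
  simulate_weighted_ensemble(spec, target, n_residues = n_residues,
                             seed = seed + 100)
}

test_that("weighted O2 reduces to the tensor expansion at uniform weights", {
  fix <- small_fixture()
  ens <- fix$ensemble
  o2_uniform <- weighted_o2(ens)
  for (id in ens$residues)
    expect_identical(o2_uniform[[id]], o2_tensor(ens$vectors[[id]]))
  # all mass on one frame: a single vector is rigid
  w1 <- c(1, rep(0, ens$n_frames - 1))
  expect_equal(unname(weighted_o2(ens, w1)), rep(1, 3), tolerance = 1e-12)
  expect_error(weighted_o2(ens, rep(0, ens$n_frames)), "all zero")
})

test_that("likelihood-ratio weights back-calculate the target O2", {
  fix <- small_fixture(n_frames = 20000, n_residues = 1, seed = 3)
  ens <- fix$ensemble
  ratio <- (fix$populations_target / fix$spec_prior$populations)
  w <- ratio[ens$wells[[1]]]
  expect_lt(abs(weighted_o2(ens, w)[[1]] - fix$targets$o2_mean[1]), 0.02)
})

test_that("the objective is zero with exact gradient at the prior optimum", {
  fix <- small_fixture(seed = 4)
  targets <- fix$targets
  targets$o2_mean <- unname(weighted_o2(fix$ensemble))   # self-consistent
  ob <- reweight_objective(rep(1, 400), fix$ensemble, targets, theta = 2)
  expect_equal(ob$chi2, 0, tolerance = 1e-12)
  expect_equal(ob$s_rel, 0, tolerance = 1e-12)
  expect_equal(ob$value, 0, tolerance = 1e-12)
  expect_lt(max(abs(ob$gradient)), 1e-9)
  # theta = 0 reduces L to chi2 exactly
  ob2 <- reweight_objective(runif(400, 0.5, 2), fix$ensemble,
                            fix$targets, theta = 0)
  expect_identical(ob2$value, ob2$chi2)
})

test_that("analytic gradients match central finite differences", {
  fix <- small_fixture(n_frames = 30, seed = 5)
  set.seed(5)
  wu <- runif(30, 0.3, 2)
  ob <- reweight_objective(wu, fix$ensemble, fix$targets, theta = 0.7)
  h <- 1e-6
  num <- vapply(1:30, function(j) {
    up <- wu; up[j] <- up[j] + h
    dn <- wu; dn[j] <- dn[j] - h
    (reweight_objective(up, fix$ensemble, fix$targets, 0.7)$value -
       reweight_objective(dn, fix$ensemble, fix$targets, 0.7)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(num - ob$gradient)), 1e-6)
})

test_that("relative entropy is non-negative and vanishes only at the prior", {
  set.seed(6)
  fix <- small_fixture(n_frames = 50, seed = 6)
  targets <- fix$targets
  for (i in 1:20) {
    wu <- runif(50, 0.01, 3)
    ob <- reweight_objective(wu, fix$ensemble, targets, theta = 1)
    expect_gte(ob$s_rel, 0)
  }
  ob0 <- reweight_objective(rep(2, 50), fix$ensemble, targets, theta = 1)
  expect_equal(ob0$s_rel, 0, tolerance = 1e-12)   # scale-invariant prior
})

test_that("optimization leaves self-consistent targets at the prior", {
  fix <- small_fixture(seed = 7)
  targets <- fix$targets
  targets$o2_mean <- unname(weighted_o2(fix$ensemble))
  res <- optimize_weights(fix$ensemble, targets, theta = 1)
  expect_lt(res$chi2, 1e-6)
  expect_gt(res$neff, 0.999)
  expect_lt(max(abs(res$weights - 1 / 400)), 1e-7)
})

test_that("huge theta pins the weights to the prior", {
  fix <- small_fixture(seed = 8)
  res <- optimize_weights(fix$ensemble, fix$targets, theta = 1e6)
  expect_lt(max(abs(res$weights - 1 / 400)), 1e-4)
  expect_lt(res$s_rel, 1e-6)
})

test_that("optimized weights improve the fit over the uniform start", {
  fix <- small_fixture(n_frames = 2000, seed = 9)
  res <- optimize_weights(fix$ensemble, fix$targets, theta = 0.1)
  ob_unif <- reweight_objective(rep(1, 2000), fix$ensemble, fix$targets,
                                theta = 0.1)
  expect_lte(res$chi2 + 0.1 * res$s_rel, ob_unif$value)
  expect_lte(res$chi2, ob_unif$chi2)
  expect_true(all(abs(res$o2_after - fix$targets$o2_mean) <
                    abs(res$o2_before - fix$targets$o2_mean) + 1e-9))
})

test_that("the solution is equivariant under frame permutation", {
  fix <- small_fixture(n_frames = 300, seed = 10)
  set.seed(10)
  perm <- sample(300)
  ens_perm <- trajectory_ensemble(
    vectors = lapply(fix$ensemble$vectors, function(v) v[perm, ]),
    chi = lapply(fix$ensemble$chi, function(m) m[perm, , drop = FALSE]),
    wells = lapply(fix$ensemble$wells, function(w) w[perm]))
  res <- optimize_weights(fix$ensemble, fix$targets, theta = 0.5)
  res_perm <- optimize_weights(ens_perm, fix$targets, theta = 0.5)
  expect_lt(max(abs(res_perm$weights - res$weights[perm])), 1e-6)
})

test_that("effective frame fractions follow both definitions exactly", {
  expect_equal(neff(rep(1 / 50, 50)), 1)
  expect_equal(neff(rep(1 / 50, 50), "kish"), 1)
  one <- c(1, rep(0, 99))
  expect_equal(neff(one), 0.01, tolerance = 1e-12)
  expect_equal(neff(one, "kish"), 0.01, tolerance = 1e-12)
  half <- c(0.5, 0.5, 0, 0)
  expect_equal(neff(half), 0.5, tolerance = 1e-12)
  expect_equal(neff(half, "kish"), 0.5, tolerance = 1e-12)
})

test_that("a one-point theta grid degenerates to a single solve", {
  fix <- small_fixture(seed = 11)
  lc <- l_curve_scan(fix$ensemble, fix$targets, 1.0)
  single <- optimize_weights(fix$ensemble, fix$targets, 1.0)
  expect_equal(nrow(lc), 1L)
  expect_equal(lc$chi2, single$chi2, tolerance = 1e-8)
  expect_equal(attr(lc, "weights")[[1]], single$weights, tolerance = 1e-6)
})

test_that("self-consistent targets give a flat L-curve flagged at selection", {
  fix <- small_fixture(seed = 12)
  targets <- fix$targets
  targets$o2_mean <- unname(weighted_o2(fix$ensemble))
  lc <- l_curve_scan(fix$ensemble, targets, 10^seq(-1, 3, length.out = 5))
  expect_true(all(lc$chi2 < 1e-6))
  expect_true(all(lc$neff > 0.999))
  sel <- select_theta_elbow(lc)
  expect_equal(sel$flag, "no elbow")
  expect_equal(sel$theta, max(lc$theta))
})

test_that("elbow selection finds curvature maxima and breakpoints", {
  # chi2(theta) = 1 + theta^2 has its log-log curvature maximum near 1
  grid <- 10^seq(-2, 2, length.out = 17)
  lc <- data.frame(theta = grid, chi2 = 1 + grid^2,
                   s_rel = 1 / (1 + grid), neff = grid / (1 + grid),
                   converged = TRUE)
  class(lc) <- c("l_curve", class(lc))
  sel <- select_theta_elbow(lc)
  step <- 10^(4 / 16)
  expect_lte(abs(log10(sel$theta)), log10(step) + 1e-9)
  # two-segment piecewise-linear log-log curve: breakpoint recovered
  y <- ifelse(grid < 1, 1, grid^2)
  lc2 <- lc; lc2$chi2 <- y
  sel2 <- select_theta_elbow(lc2)
  expect_lte(abs(log10(sel2$theta)), log10(step) + 1e-9)
  # plateau method: largest theta within 10% of the small-theta chi2
  lc3 <- lc; lc3$chi2 <- c(rep(1, 9), seq(1.2, 10, length.out = 8))
  sel3 <- select_theta_elbow(lc3, method = "chi2_plateau")
  expect_equal(sel3$theta, grid[9])
})

test_that("recovery fixture keeps a smooth weight distribution at the elbow", {
  fix <- small_fixture(n_frames = 2000, n_residues = 3, seed = 13)
  lc <- l_curve_scan(fix$ensemble, fix$targets,
                     10^seq(-2, 3, length.out = 6), max_iter = 2000)
  sel <- select_theta_elbow(lc)
  expect_gt(lc$neff[sel$index], 0.3)
})

test_that("weight and target tables round-trip", {
  fix <- small_fixture(seed = 14)
  res <- optimize_weights(fix$ensemble, fix$targets, theta = 1)
  wpath <- withr::local_tempfile(fileext = ".tsv")
  write_weights(res$weights, wpath)
  expect_equal(read_weights(wpath), res$weights, tolerance = 1e-12)
  tpath <- withr::local_tempfile(fileext = ".tsv")
  write_targets(fix$targets, tpath)
  expect_equal(read_targets(tpath)$o2_mean, fix$targets$o2_mean,
               tolerance = 1e-12)
})
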