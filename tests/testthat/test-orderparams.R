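random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  sv <- svd(m)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_that("superposition recovers known rigid-body transforms", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  # identity
  s <- superpose_frames(list(ref), ref)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$rotations[[1]], diag(3), tolerance = 1e-9)
  # known rotation + translation: recovered as its transpose, RMSD 0
  R <- random_rotation()
  moved <- sweep(ref %*% R, 2, c(3, -2, 7), "+")
  s2 <- superpose_frames(list(moved), ref)
  expect_equal(s2$rmsd, 0, tolerance = 1e-9)
  expect_equal(s2$frames[[1]], ref, tolerance = 1e-9)
  expect_equal(s2$rotations[[1]], t(R), tolerance = 1e-9)
  # proper rotation enforced even for a reflected conformer
  expect_equal(det(superpose_frames(list(-ref), ref)$rotations[[1]]), 1,
               tolerance = 1e-9)
})

test_that("superposition matches the bio3d reference implementation", {
  set.seed(2)
  ref <- matrix(rnorm(36), 12, 3)
  mob <- ref + matrix(rnorm(36, 0, 0.3), 12, 3)
  ours <- superpose_frames(list(mob), ref)
  b3d <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)), fit = TRUE)
  # bio3d rounds its reported RMSD to three decimals
  expect_lt(abs(ours$rmsd[1] - b3d), 1e-3)
})

test_that("degenerate atom selections are rejected", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose_frames(list(line), line), "collinear")
  ref <- matrix(rnorm(30), 10, 3)
  expect_error(superpose_frames(list(ref), ref, selection = 1:2),
               "at least 3")
})

test_that("dihedral angles follow the IUPAC sign convention", {
  base <- function(chi_deg) {
    # butane-like chain: p2-p3 along z, p1 in the xz plane, p4 rotated by chi
    chi <- chi_deg * pi / 180
    rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1),
          c(cos(chi), sin(chi), 2))
  }
  for (chi in c(0, 60, 180, -60, 135.5)) {
    g <- base(chi)
    expected <- ((chi + 180) %% 360) - 180
    if (expected == -180) expected <- 180   # convention: (-180, 180]
    expect_equal(compute_dihedral(g[1, ], g[2, ], g[3, ], g[4, ]),
                 expected, tolerance = 1e-9)
  }
  # mirror image flips the sign
  g <- base(60); m <- g %*% diag(c(1, -1, 1))
  expect_equal(compute_dihedral(m[1, ], m[2, ], m[3, ], m[4, ]), -60,
               tolerance = 1e-9)
  # degenerate (collinear) geometry is undefined
  expect_error(compute_dihedral(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                                c(0, 0, 3)), "degenerate")
})

test_that("dihedrals agree with the bio3d torsion routine", {
  set.seed(3)
  for (i in 1:5) {
    pts <- matrix(rnorm(12), 4, 3)
    ours <- compute_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
    expect_equal(((ours - ref + 180) %% 360) - 180, 0, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("methyl axes are extracted in both parameterizations", {
  # hand-built quartet: chain in a plane (phi = 180) with a 100-degree
  # bond angle at the sulfur
  theta <- 100 * pi / 180
  # Cb sits off the Cg-Sd axis (+x); Ce's azimuth opposite (-x) gives
  # chi3 = 180 by construction
  geom <- rbind(cb = c(1, 0, -2),
                cg = c(0, 0, -1),
                sd = c(0, 0, 0),
                ce = 1.8 * c(-sin(pi - theta), 0, cos(pi - theta)))
  atoms <- data.frame(atom = c("CB", "CG", "SD", "CE"), resid = "244",
                      resname = "MET")
  ax <- extract_methyl_axes(list(geom), atoms)
  expect_equal(unname(abs(ax$cart$chi[["244"]][1, "chi3"])), 180,
               tolerance = 1e-9)
  expect_equal(ax$theta[["244"]][1], 100, tolerance = 1e-9)
  # vector form points along Sd - Ce
  v <- geom["sd", ] - geom["ce", ]
  expect_equal(ax$cart$vectors[["244"]][1, ], v / sqrt(sum(v^2)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # rigid-body rotation leaves the internal (angle) parameterization fixed
  R <- random_rotation()
  ax_rot <- extract_methyl_axes(list(geom %*% R), atoms)
  expect_equal(ax_rot$angle$vectors[["244"]], ax$angle$vectors[["244"]],
               tolerance = 1e-9)
  # missing atoms: residue skipped with warning
  expect_warning(
    expect_error(extract_methyl_axes(list(geom[1:3, ]), atoms[1:3, ]),
                 "no residue"),
    "missing atoms")
})

test_that("tensor order parameter hits its closed-form limits", {
  v <- matrix(rep(c(0.6, 0.64, 0.48), each = 5), 5, 3)
  expect_equal(o2_tensor(v / sqrt(rowSums(v^2))), 1, tolerance = 1e-12)
  set.seed(4)
  z <- matrix(rnorm(3e5), ncol = 3)
  z <- z / sqrt(rowSums(z^2))
  expect_lt(abs(o2_tensor(z)), 0.01)
  # exact three-vector evaluation: equal jump about the axis gives 1/9
  u3 <- axis_from_angles(109.47, c(60, 180, -60))
  expect_equal(o2_tensor(u3, rep(1, 3) / 3),
               ((3 * cos(109.47 * pi / 180)^2 - 1) / 2)^2,
               tolerance = 1e-12)
  expect_warning(o2_tensor(u3, c(1, 1, 1)), "normaliz")
})

test_that("O2 is invariant under a global rotation of all frames", {
  traj <- simulate_rotamer_trajectory(met_jump_spec(5000, seed = 5))
  set.seed(6); R <- random_rotation()
  expect_equal(o2_tensor(traj$vectors %*% R), o2_tensor(traj$vectors),
               tolerance = 1e-12)
})

test_that("internal TCF has the right limits and plateau", {
  # constant vector: C = 1 everywhere
  v <- matrix(rep(c(1, 0, 0), each = 10), 10, 3)
  tcf <- internal_tcf(v, max_lag = 4)
  expect_equal(tcf$values, rep(1, 5), tolerance = 1e-12)
  # alternating orthogonal vectors: odd lags give P2(0) = -1/2
  alt <- matrix(rep(c(1, 0, 0, 0, 1, 0), 50), ncol = 3, byrow = TRUE)
  tcf_alt <- internal_tcf(alt, max_lag = 5)
  expect_equal(tcf_alt$values[c(2, 4, 6)], rep(-0.5, 3), tolerance = 1e-12)
  expect_equal(tcf_alt$values[c(1, 3, 5)], rep(1, 3), tolerance = 1e-12)
  expect_error(internal_tcf(alt, max_lag = 60), "max_lag")
})

test_that("TCF plateau agrees with the tensor value on converged jumps", {
  traj <- simulate_rotamer_trajectory(met_jump_spec(1e5, seed = 7))
  tcf <- internal_tcf(traj$vectors, max_lag = 300, origin_stride = 5)
  expect_lt(abs(tcf_plateau(tcf) - o2_tensor(traj$vectors)), 0.02)
  # tail_mean on a linear tail averages it
  lin <- structure(list(lags = 0:99,
                        values = c(rep(1, 90), seq(0.30, 0.20,
                                                   length.out = 10)),
                        parameterization = "vector"),
                   class = "time_correlation")
  expect_equal(tcf_plateau(lin, "tail_mean", window = 0.1), 0.25,
               tolerance = 1e-12)
  expect_equal(tcf_plateau(lin), 0.20)
})

test_that("angle parameterization shields O2 from residual global motion", {
  spec <- met_jump_spec(4000, libration_sd = 10, seed = 8)
  traj <- simulate_rotamer_trajectory(spec)
  # residual global wobble: small random rotation per frame
  set.seed(9)
  wob <- t(vapply(seq_len(nrow(traj$vectors)), function(i) {
    ang <- rnorm(3, 0, 0.12)
    Rz <- rbind(c(cos(ang[1]), -sin(ang[1]), 0),
                c(sin(ang[1]), cos(ang[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[2]), -sin(ang[2])),
                c(0, sin(ang[2]), cos(ang[2])))
    drop(traj$vectors[i, ] %*% (Rz %*% Rx))
  }, numeric(3)))
  o2_vector <- o2_tensor(wob)                      # sees the wobble
  o2_angle <- o2_tensor(traj$vectors)              # internal coordinates
  expect_gt(o2_angle, o2_vector)
})

test_that("pooled-origin TCF matches the average over identical replicas", {
  spec <- met_jump_spec(20000, seed = 10)
  traj <- simulate_rotamer_trajectory(spec)
  halves <- list(traj$vectors[1:10000, ], traj$vectors[10001:20000, ])
  per_rep <- vapply(halves, function(v)
    internal_tcf(v, max_lag = 50, origin_stride = 2)$values, numeric(51))
  pooled <- internal_tcf(traj$vectors, max_lag = 50,
                         origin_stride = 2)$values
  expect_lt(max(abs(rowMeans(per_rep) - pooled)), 0.05)
})
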