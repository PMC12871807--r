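#' Least-squares superposition of trajectory frames onto a reference
#'
#' Removes overall rotational and translational diffusion by optimal
#' rigid-body superposition (Kabsch algorithm, proper rotation enforced) of
#' a selected atom subset — typically the backbone C-alpha atoms — onto a
#' reference structure. The fitted transform of the selection is applied to
#' all atoms of each frame.
#'
#' @param frames list of n_atoms x 3 coordinate matrices, one per frame.
#' @param reference n_atoms x 3 reference coordinate matrix.
#' @param selection integer or logical index of atoms used for the fit
#'   (default all). At least 3 non-collinear atoms.
#' @return List with `frames` (aligned coordinates), `rmsd` (per-frame
#'   fitted RMSD over the selection), and `rotations` (list of 3 x 3
#'   proper rotation matrices).
#' @export
superpose_frames <- function(frames, reference, selection = NULL) {
  stopifnot(is.list(frames), is.matrix(reference), ncol(reference) == 3)
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  ref_sel <- reference[selection, , drop = FALSE]
  if (nrow(ref_sel) < 3)
    stop("selection must contain at least 3 atoms")
  refc <- sweep(ref_sel, 2, colMeans(ref_sel))
  if (qr(refc)$rank < 2)
    stop("selection is collinear/degenerate: superposition is not unique")
  ref_centroid <- colMeans(ref_sel)
  out <- vector("list", length(frames))
  rmsd <- numeric(length(frames))
  rots <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    P <- frames[[i]]
    P_sel <- P[selection, , drop = FALSE]
    pc <- colMeans(P_sel)
    H <- crossprod(sweep(P_sel, 2, pc), refc)
    sv <- svd(H)
    d <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    aligned <- sweep(P, 2, pc) %*% R
    aligned <- sweep(aligned, 2, ref_centroid, "+")
    out[[i]] <- aligned
    rots[[i]] <- R
    diff <- aligned[selection, , drop = FALSE] - ref_sel
    rmsd[i] <- sqrt(mean(rowSums(diff^2)))
  }
  list(frames = out, rmsd = rmsd, rotations = rots)
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: cis = 0 degrees, angles in (-180, 180],
#' positive for a clockwise rotation of the far bond viewed along the
#' central bond. Vectorized over coordinate rows.
#'
#' @param p1,p2,p3,p4 length-3 vectors or n x 3 matrices of coordinates.
#' @return Dihedral angle(s) in degrees.
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- sqrt(rowSums(b2^2))
  if (any(b2n == 0) || any(rowSums(n1^2) == 0) || any(rowSums(n2^2) == 0))
    stop("degenerate geometry: dihedral undefined")
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * (b2 / b2n))
  wrap_angle(atan2(y, x) * 180 / pi)
}

# interior angle (degrees) at p2 formed by p1-p2-p3, vectorized
bond_angle <- function(p1, p2, p3) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3)
  a <- p1 - p2; b <- p3 - p2
  ct <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Extract methyl-axis parameterizations from coordinates
#'
#' For each selected residue (methionine by default) with the four atoms
#' Cb, Cg, Sd, Ce present, emits both parameterizations of the methyl-axis
#' unit vector per frame: the Cartesian form (normalized Sd - Ce vector in
#' the, typically superposed, molecular frame) and the local
#' spherical-coordinate form rebuilt from the polar bond angle theta
#' (Cg-Sd-Ce) and the azimuthal dihedral phi (Cb-Cg-Sd-Ce, i.e. chi3). The
#' angle form is frame-internal and therefore insensitive to residual
#' global motion by construction.
#'
#' @param frames list of n_atoms x 3 coordinate matrices (one per frame),
#'   usually the output of [superpose_frames()].
#' @param atoms data.frame describing rows of the coordinate matrices, with
#'   columns `atom` (name), `resid` (residue identifier) and optionally
#'   `resname`.
#' @param residues residue identifiers to process (default: all with a
#'   complete atom quartet). Residues missing atoms are skipped with a
#'   warning.
#' @param atom_names named map of the four atom names, default
#'   `c(cb = "CB", cg = "CG", sd = "SD", ce = "CE")`.
#' @return List with `cart` and `angle` ([trajectory_ensemble()] objects,
#'   chi3 attached to both) plus `theta` (per-residue bond-angle series).
#' @export
extract_methyl_axes <- function(frames, atoms, residues = NULL,
                                atom_names = c(cb = "CB", cg = "CG",
                                               sd = "SD", ce = "CE")) {
  stopifnot(is.list(frames), is.data.frame(atoms),
            all(c("atom", "resid") %in% names(atoms)))
  if (is.null(residues)) residues <- unique(atoms$resid)
  vec_cart <- list(); vec_angle <- list(); chis <- list(); thetas <- list()
  for (rid in residues) {
    idx <- vapply(atom_names, function(an) {
      w <- which(atoms$resid == rid & atoms$atom == an)
      if (length(w) == 1L) w else NA_integer_
    }, integer(1))
    if (anyNA(idx)) {
      warning(sprintf("residue %s: missing atoms, skipped", rid))
      next
    }
    cb <- t(vapply(frames, function(f) f[idx["cb"], ], numeric(3)))
    cg <- t(vapply(frames, function(f) f[idx["cg"], ], numeric(3)))
    sd_ <- t(vapply(frames, function(f) f[idx["sd"], ], numeric(3)))
    ce <- t(vapply(frames, function(f) f[idx["ce"], ], numeric(3)))
    v <- sd_ - ce
    v <- v / sqrt(rowSums(v^2))
    dimnames(v) <- list(NULL, c("x", "y", "z"))
    theta <- bond_angle(cg, sd_, ce)
    phi <- compute_dihedral(cb, cg, sd_, ce)
    key <- as.character(rid)
    vec_cart[[key]] <- v
    vec_angle[[key]] <- axis_from_angles_series(theta, phi)
    chis[[key]] <- matrix(phi, ncol = 1, dimnames = list(NULL, "chi3"))
    thetas[[key]] <- theta
  }
  if (!length(vec_cart)) stop("no residue had a complete atom quartet")
  rn <- setNames(rep("MET", length(vec_cart)), names(vec_cart))
  if ("resname" %in% names(atoms)) {
    for (key in names(vec_cart)) {
      nm <- unique(atoms$resname[atoms$resid == key])
      if (length(nm) == 1L) rn[key] <- nm
    }
  }
  list(cart = trajectory_ensemble(vec_cart, chi = chis, residue_names = rn),
       angle = trajectory_ensemble(vec_angle, chi = chis, residue_names = rn),
       theta = thetas)
}

# Eq-7 vector with per-frame theta (unlike axis_from_angles' fixed theta)
axis_from_angles_series <- function(theta, chi) {
  pt <- pi - theta * pi / 180
  phi <- chi * pi / 180
  cbind(x = sin(pt) * cos(phi), y = sin(pt) * sin(phi), z = cos(pt))
}

#' Methyl-axis order parameter by the second-rank tensor expansion
#'
#' \deqn{O^2 = \tfrac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2
#'   + \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
#'   2\langle yz\rangle^2\right] - \tfrac{1}{2}}
#' with (weighted) averages over frames. Ranges from 0 (isotropic
#' disorder) to 1 (complete rigidity). The same code path serves uniform
#' and reweighted ensembles.
#'
#' @param vectors n x 3 matrix of unit bond vectors.
#' @param weights optional per-frame weights; normalized (with a warning if
#'   not already normalized), default uniform.
#' @return Scalar O2 in \[0, 1\].
#' @export
o2_tensor <- function(vectors, weights = NULL) {
  stopifnot(is.matrix(vectors), ncol(vectors) == 3, nrow(vectors) >= 1)
  n <- nrow(vectors)
  if (is.null(weights)) {
    weights <- rep(1 / n, n)
  } else {
    if (length(weights) != n || any(weights < 0))
      stop("`weights` must be non-negative, one per frame")
    s <- sum(weights)
    if (s <= 0) stop("`weights` must not be all zero")
    if (abs(s - 1) > 1e-9) {
      warning("weights not normalized; normalizing")
    }
    weights <- weights / s
  }
  o2_from_products(crossprod(o2_frame_products(vectors), weights))
}

# per-frame tensor products [x2 y2 z2 xy xz yz], the sufficient statistics
# of the tensor expansion (and of its weighted form)
o2_frame_products <- function(vectors) {
  x <- vectors[, 1]; y <- vectors[, 2]; z <- vectors[, 3]
  cbind(x2 = x^2, y2 = y^2, z2 = z^2, xy = x * y, xz = x * z, yz = y * z)
}

# O2 from the 6 averaged tensor components
o2_from_products <- function(m) {
  m <- as.numeric(m)
  1.5 * (m[1]^2 + m[2]^2 + m[3]^2 +
           2 * (m[4]^2 + m[5]^2 + m[6]^2)) - 0.5
}

#' Internal time correlation function of a bond vector
#'
#' \deqn{C_{int}(\tau) = \langle P_2(\hat\mu(t)\cdot\hat\mu(t+\tau))
#'   \rangle_t, \qquad P_2(x) = (3x^2-1)/2,}
#' averaged over time origins t. Its long-time plateau equals the
#' tensor-expansion order parameter. `C_int(0) = 1` by construction.
#'
#' @param vectors n x 3 matrix of unit bond vectors (time ordered).
#' @param max_lag maximum lag in frames; must be < n/2 so every lag
#'   retains at least half the origins.
#' @param origin_stride use every `origin_stride`-th frame as an origin
#'   (1 = dense origins).
#' @param parameterization tag recorded in the result (`"vector"` or
#'   `"angle"`).
#' @return Object of class `"time_correlation"` with `lags` and `values`.
#' @export
internal_tcf <- function(vectors, max_lag, origin_stride = 1L,
                         parameterization = "vector") {
  n <- nrow(vectors)
  if (max_lag >= n / 2)
    stop("`max_lag` must be smaller than half the trajectory length")
  lags <- 0:max_lag
  vals <- vapply(lags, function(tau) {
    i <- seq.int(1L, n - tau, by = origin_stride)
    d <- rowSums(vectors[i, , drop = FALSE] *
                   vectors[i + tau, , drop = FALSE])
    mean((3 * d^2 - 1) / 2)
  }, numeric(1))
  structure(list(lags = lags, values = vals,
                 parameterization = parameterization),
            class = "time_correlation")
}

#' @export
print.time_correlation <- function(x, ...) {
  cat(sprintf("<time_correlation> (%s) %d lags, C(0) = %.6f, C(max) = %.4f\n",
              x$parameterization, length(x$lags), x$values[1],
              tail(x$values, 1)))
  invisible(x)
}

#' Order parameter from the TCF plateau
#'
#' Default mode `"last_point"` reads off the final TCF value; `"tail_mean"`
#' averages over the trailing `window` fraction of lags.
#'
#' @param tcf a [internal_tcf()] result.
#' @param mode `"last_point"` or `"tail_mean"`.
#' @param window trailing fraction averaged in `"tail_mean"` mode.
#' @return Scalar plateau estimate of O2.
#' @export
tcf_plateau <- function(tcf, mode = c("last_point", "tail_mean"),
                        window = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(tcf, "time_correlation"))
  if (mode == "last_point") return(tail(tcf$values, 1))
  k <- max(1L, ceiling(window * length(tcf$values)))
  mean(tail(tcf$values, k))
}
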