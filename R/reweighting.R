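#' Back-calculated order parameters under ensemble weights
#'
#' Weighted form of the second-rank tensor expansion: the six tensor
#' components are weighted frame averages, and O2 depends quadratically on
#' them, hence non-linearly on the weights. At uniform weights this reduces
#' exactly to [o2_tensor()] (shared code path).
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param weights per-frame weights, possibly unnormalized (normalized
#'   internally); all non-negative, not all zero.
#' @return Named numeric vector of O2 per residue.
#' @export
weighted_o2 <- function(ensemble, weights = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (is.null(weights)) weights <- ensemble$weights
  if (length(weights) != ensemble$n_frames || any(weights < 0))
    stop("`weights` must be non-negative, one per frame")
  if (sum(weights) <= 0) stop("`weights` must not be all zero")
  w <- weights / sum(weights)
  vapply(ensemble$vectors, function(v) o2_tensor(v, w), numeric(1))
}

# Precompute per-residue frame-product matrices once per solve
reweight_products <- function(ensemble, targets) {
  missing <- setdiff(targets$residue_id, ensemble$residues)
  if (length(missing))
    stop("targets refer to residues absent from the ensemble: ",
         paste(missing, collapse = ", "))
  if (any(targets$o2_sd <= 0)) stop("target sds must be > 0")
  lapply(targets$residue_id,
         function(id) o2_frame_products(ensemble$vectors[[id]]))
}

#' Reweighting objective and analytic gradient
#'
#' Evaluates \eqn{L(w) = \chi^2(w) + \theta S_{REL}(w)} with
#' \eqn{\chi^2(w) = \sum_i (O^2_i(w) - O^2_{NMR,i})^2/\sigma_i^2} and
#' \eqn{S_{REL}(w) = \sum_j w_j \ln(w_j/w^0_j)}, together with its exact
#' gradient with respect to the *unnormalized* weights `wu` (the weights
#' actually optimized; normalization is part of the function, so the
#' gradient carries the simplex projection term).
#'
#' @param wu unnormalized non-negative weights (length n_frames).
#' @param ensemble a [trajectory_ensemble()].
#' @param targets data.frame with `residue_id`, `o2_mean`, `o2_sd`.
#' @param theta regularization strength (>= 0).
#' @param prior prior weights w0 (default uniform 1/N). Normalized.
#' @param products optional precomputed [reweight_products()] cache.
#' @return List with `value`, `gradient`, `chi2`, `s_rel`, and `o2`
#'   (per-target back-calculated values).
#' @export
reweight_objective <- function(wu, ensemble, targets, theta,
                               prior = NULL, products = NULL) {
  if (any(!is.finite(wu))) stop("weights must be finite")
  # box-constrained optimizers can return bound values off by round-off
  wu[wu < 0 & wu > -1e-9] <- 0
  if (any(wu < 0)) stop("weights must be >= 0")
  if (theta < 0) stop("`theta` must be >= 0")
  n <- length(wu)
  if (is.null(products)) products <- reweight_products(ensemble, targets)
  if (is.null(prior)) prior <- rep(1 / n, n)
  prior <- prior / sum(prior)
  W <- sum(wu)
  if (W <= 0) stop("weights must not be all zero")
  w <- wu / W

  chi2 <- 0
  g_chi_w <- numeric(n)  # d chi2 / d w
  o2 <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    A <- products[[i]]
    m <- unname(drop(crossprod(A, w)))
    o2_i <- 1.5 * (m[1]^2 + m[2]^2 + m[3]^2 +
                     2 * (m[4]^2 + m[5]^2 + m[6]^2)) - 0.5
    o2[i] <- o2_i
    resid <- (o2_i - targets$o2_mean[i]) / targets$o2_sd[i]^2
    chi2 <- chi2 + resid * (o2_i - targets$o2_mean[i])
    dm <- 3 * c(m[1], m[2], m[3], 2 * m[4], 2 * m[5], 2 * m[6])
    g_chi_w <- g_chi_w + 2 * resid * drop(A %*% dm)
  }

  pos <- w > 0
  logratio <- numeric(n)
  logratio[pos] <- log(w[pos] / prior[pos])
  s_rel <- sum(w[pos] * logratio[pos])
  # one-sided derivative at the w = 0 boundary (floor the log)
  logratio[!pos] <- log(.Machine$double.xmin) - log(prior[!pos])
  g_s_w <- logratio + 1

  g_w <- g_chi_w + theta * g_s_w
  # chain rule through normalization: du_j picks up the tangent projection
  grad <- (g_w - sum(w * g_w)) / W
  list(value = chi2 + theta * s_rel, gradient = grad,
       chi2 = chi2, s_rel = s_rel, o2 = setNames(o2, targets$residue_id))
}

#' Optimize ensemble weights against order-parameter targets
#'
#' Direct box-constrained quasi-Newton (L-BFGS-B) minimization of
#' \eqn{L(w) = \chi^2(w) + \theta S_{REL}(w)} over non-negative
#' unnormalized weights, using the analytic gradient of
#' [reweight_objective()]. The Lagrange-multiplier route of linear-average
#' maximum-entropy reweighting does not apply because O2 is quadratic in
#' the averaged tensor components.
#'
#' @inheritParams reweight_objective
#' @param init initial unnormalized weights (default uniform).
#' @param tol projected-gradient tolerance passed to the optimizer.
#' @param max_iter iteration cap.
#' @return Object of class `"reweight_result"`: normalized `weights`,
#'   `theta`, `chi2`, `s_rel`, `neff` (exp(-S_REL)), per-target
#'   `o2_before`/`o2_after`, optimizer `status`, and `boundary_frames`
#'   (indices with zero weight).
#' @examples
#' fix <- simulate_weighted_ensemble(
#'   rotamer_jump_spec(c(60, 180, -60), n_frames = 500),
#'   populations_target = c(0.6, 0.2, 0.2), n_residues = 2, seed = 1)
#' res <- optimize_weights(fix$ensemble, fix$targets, theta = 0.01)
#' @export
optimize_weights <- function(ensemble, targets, theta, init = NULL,
                             prior = NULL, tol = 1e-8, max_iter = 5000L) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  n <- ensemble$n_frames
  products <- reweight_products(ensemble, targets)
  if (is.null(init)) init <- rep(1, n)
  if (is.null(prior)) prior <- rep(1 / n, n)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(wu) {
    if (!is.null(cache$wu) && identical(wu, cache$wu)) return(cache$res)
    res <- reweight_objective(wu, ensemble, targets, theta, prior, products)
    cache$wu <- wu; cache$res <- res
    res
  }
  opt <- optim(init, fn = function(wu) evaluate(wu)$value,
               gr = function(wu) evaluate(wu)$gradient,
               method = "L-BFGS-B", lower = 0,
               control = list(maxit = max_iter, factr = 1e1, pgtol = tol))
  final <- reweight_objective(opt$par, ensemble, targets, theta, prior,
                              products)
  w <- opt$par / sum(opt$par)
  structure(list(
    weights = w, theta = theta, chi2 = final$chi2, s_rel = final$s_rel,
    neff = exp(-final$s_rel),
    o2_before = weighted_o2(ensemble, prior),
    o2_after = final$o2,
    targets = targets,
    boundary_frames = which(w == 0),
    status = list(converged = opt$convergence == 0,
                  iterations = opt$counts[["function"]],
                  message = opt$message,
                  grad_norm = max(abs(final$gradient)))),
    class = "reweight_result")
}

#' @export
print.reweight_result <- function(x, ...) {
  cat(sprintf(
    "<reweight_result> theta = %g: chi2 = %.4g, S_rel = %.4g, Neff = %.3f%s\n",
    x$theta, x$chi2, x$s_rel, x$neff,
    if (x$status$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Effective fraction of frames retained by a weight vector
#'
#' Default definition `exp(-S_REL)` (relative-entropy based, standard in
#' maximum-entropy ensemble refinement); the Kish effective-sample-size
#' ratio \eqn{(\sum w)^2 / (N \sum w^2)} is selectable. Both lie in
#' (0, 1\] and equal 1 iff the weights match the prior (uniform for Kish).
#'
#' @param weights normalized weights.
#' @param method `"entropy"` or `"kish"`.
#' @param prior prior weights for the entropy definition (default uniform).
#' @return Scalar effective fraction.
#' @export
neff <- function(weights, method = c("entropy", "kish"), prior = NULL) {
  method <- match.arg(method)
  w <- weights / sum(weights)
  if (method == "kish") return(1 / (length(w) * sum(w^2)))
  if (is.null(prior)) prior <- rep(1 / length(w), length(w))
  prior <- prior / sum(prior)
  pos <- w > 0
  exp(-sum(w[pos] * log(w[pos] / prior[pos])))
}

#' L-curve scan over the regularization strength
#'
#' Runs [optimize_weights()] over a log-spaced theta grid in descending
#' order, warm-starting each solve from the previous solution, and tabulates
#' chi2, S_REL and Neff per theta. Individual failures are recorded and the
#' scan continues.
#'
#' @inheritParams optimize_weights
#' @param theta_grid regularization strengths (>= 5 values recommended for
#'   elbow selection).
#' @return Object of class `"l_curve"`: a data.frame with columns `theta`,
#'   `chi2`, `s_rel`, `neff`, `converged`, plus the per-theta weight
#'   vectors in `attr(, "weights")`.
#' @export
l_curve_scan <- function(ensemble, targets, theta_grid, prior = NULL,
                         tol = 1e-8, max_iter = 5000L) {
  theta_grid <- sort(theta_grid, decreasing = TRUE)
  n <- ensemble$n_frames
  init <- rep(1, n)
  rows <- vector("list", length(theta_grid))
  wlist <- vector("list", length(theta_grid))
  for (i in seq_along(theta_grid)) {
    res <- tryCatch(
      optimize_weights(ensemble, targets, theta_grid[i], init = init,
                       prior = prior, tol = tol, max_iter = max_iter),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(theta = theta_grid[i], chi2 = NA_real_,
                              s_rel = NA_real_, neff = NA_real_,
                              converged = FALSE)
      next
    }
    rows[[i]] <- data.frame(theta = theta_grid[i], chi2 = res$chi2,
                            s_rel = res$s_rel, neff = res$neff,
                            converged = res$status$converged)
    wlist[[i]] <- res$weights
    init <- res$weights * n  # warm start for the next (smaller) theta
  }
  out <- do.call(rbind, rows)
  attr(out, "weights") <- wlist
  class(out) <- c("l_curve", class(out))
  out
}

#' Select theta at the elbow of the L-curve
#'
#' `"max_curvature"` (default) locates the maximum discrete curvature of
#' log(chi2) against log(theta); `"chi2_plateau"` returns the largest theta
#' whose chi2 is within `rel_tol` of the chi2 at the smallest theta. A flat
#' curve yields the largest theta with a `"no elbow"` flag.
#'
#' @param lcurve an [l_curve_scan()] result (>= 5 grid points).
#' @param method `"max_curvature"` or `"chi2_plateau"`.
#' @param rel_tol relative tolerance for the plateau method.
#' @return List with `theta`, `index` (row of `lcurve`), and `flag`
#'   (`"ok"` or `"no elbow"`).
#' @export
select_theta_elbow <- function(lcurve,
                               method = c("max_curvature", "chi2_plateau"),
                               rel_tol = 0.1) {
  method <- match.arg(method)
  ok <- is.finite(lcurve$chi2)
  lc <- lcurve[ok, , drop = FALSE]
  lc <- lc[order(lc$theta), , drop = FALSE]
  if (nrow(lc) < 5) stop("at least 5 valid grid points are required")
  chi2 <- pmax(lc$chi2, .Machine$double.xmin)
  flat <- diff(range(log(chi2))) < 1e-6
  if (flat) {
    i <- which.max(lc$theta)
    return(list(theta = lc$theta[i],
                index = which(lcurve$theta == lc$theta[i])[1],
                flag = "no elbow"))
  }
  if (method == "chi2_plateau") {
    ref <- chi2[1]  # smallest theta
    tol_abs <- rel_tol * max(ref, .Machine$double.eps)
    cand <- which(chi2 <= ref + tol_abs)
    i <- cand[which.max(lc$theta[cand])]
  } else {
    x <- log(lc$theta); y <- log(chi2)
    m <- nrow(lc)
    kappa <- rep(NA_real_, m)
    for (j in 2:(m - 1)) {
      h1 <- x[j] - x[j - 1]; h2 <- x[j + 1] - x[j]
      d1 <- (y[j + 1] - y[j - 1]) / (h1 + h2)
      d2 <- 2 * (h1 * y[j + 1] - (h1 + h2) * y[j] + h2 * y[j - 1]) /
        (h1 * h2 * (h1 + h2))
      kappa[j] <- abs(d2) / (1 + d1^2)^1.5
    }
    i <- which.max(kappa)
  }
  list(theta = lc$theta[i], index = which(lcurve$theta == lc$theta[i])[1],
       flag = "ok")
}

#' Write an L-curve table
#'
#' TSV schema: `theta`, `chi2`, `s_rel`, `neff`, `converged`.
#'
#' @param lcurve an [l_curve_scan()] result.
#' @param path file path.
#' @export
write_lcurve <- function(lcurve, path) {
  write.table(as.data.frame(lcurve)[, c("theta", "chi2", "s_rel", "neff",
                                        "converged")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
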