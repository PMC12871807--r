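# chi-angle counts per standard residue; side-chain entropy is computed for
# residues with 1..3 chi angles (LYS/ARG have more and are intractable at
# this histogram resolution; GLY has none; ALA's methyl chi is symmetric and
# carries no conformational entropy)
CHI_COUNTS <- c(
  ALA = 1, ARG = 5, ASN = 2, ASP = 2, CYS = 1, GLN = 3, GLU = 3, GLY = 0,
  HIS = 2, ILE = 2, LEU = 2, LYS = 4, MET = 3, PHE = 2, PRO = 2, SER = 1,
  THR = 1, TRP = 2, TYR = 2, VAL = 1)

#' Residue eligibility for side-chain entropy calculations
#'
#' Includes residues with one to three chi angles; excludes glycine (no chi
#' angle), alanine (its single methyl rotation is symmetric and contributes
#' no conformational entropy), and lysine/arginine (more than three chi
#' angles, for which the histogram estimate does not converge). Unknown
#' codes are excluded with a warning.
#'
#' @param resnames character vector of three-letter residue codes.
#' @return data.frame with `resname`, `n_chi`, `included`, `reason`.
#' @examples
#' eligible_residues(c("MET", "GLY", "LYS", "SER"))
#' @export
eligible_residues <- function(resnames) {
  resnames <- toupper(resnames)
  n_chi <- unname(CHI_COUNTS[resnames])
  included <- logical(length(resnames))
  reason <- character(length(resnames))
  for (i in seq_along(resnames)) {
    if (is.na(n_chi[i])) {
      reason[i] <- "unknown residue code"
      warning("unknown residue code: ", resnames[i])
    } else if (resnames[i] == "GLY") {
      reason[i] <- "no chi angle"
    } else if (resnames[i] == "ALA") {
      reason[i] <- "symmetric methyl chi, no conformational entropy"
    } else if (n_chi[i] > 3) {
      reason[i] <- "more than 3 chi angles"
    } else {
      included[i] <- TRUE
      reason[i] <- ""
    }
  }
  data.frame(resname = resnames, n_chi = n_chi, included = included,
             reason = reason, stringsAsFactors = FALSE)
}

#' Weighted dihedral-angle histogram
#'
#' Discretizes a chi-angle series into fixed-width bins over (-180, 180\]
#' (10 degrees by default, 36 bins) and accumulates the frame weights per
#' bin: \eqn{P(k) = \sum_{j \in bin\,k} w_j}. Bins are right-closed with
#' edges at -180 + k * width (shiftable by `offset` for sensitivity
#' analysis); angles are wrapped onto the circle first, so the binning is
#' wrap-around consistent. Non-finite angles are dropped with their weight
#' and counted.
#'
#' @param angles chi angles in degrees.
#' @param weights per-frame weights (default uniform); renormalized over
#'   the retained frames.
#' @param bin_width bin width in degrees; must divide 360.
#' @param offset edge shift in degrees.
#' @return Object of class `"dihedral_histogram"`: list with `probs`
#'   (named by bin centre, sum 1), `edges`, `bin_width`, `n_dropped`.
#' @export
weighted_dihedral_histogram <- function(angles, weights = NULL,
                                        bin_width = 10, offset = 0) {
  if (360 %% bin_width != 0) stop("`bin_width` must divide 360")
  n <- length(angles)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) stop("`weights` must match `angles` in length")
  keep <- is.finite(angles)
  n_dropped <- sum(!keep)
  angles <- angles[keep]; weights <- weights[keep]
  if (!length(angles)) stop("no finite angles to histogram")
  weights <- weights / sum(weights)
  edges <- seq(-180, 180, by = bin_width)
  # wrap into (-180 + offset, 180 + offset], then shift back to the
  # reference edges
  x <- wrap_angle(angles - offset)
  k <- findInterval(x, edges, left.open = TRUE, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  nb <- length(edges) - 1L
  probs <- vapply(seq_len(nb), function(b) sum(weights[k == b]), numeric(1))
  names(probs) <- (edges[-length(edges)] + edges[-1]) / 2 + offset
  structure(list(probs = probs, edges = edges + offset,
                 bin_width = bin_width, n_dropped = n_dropped),
            class = "dihedral_histogram")
}

#' Side-chain conformational entropy of one residue
#'
#' Gibbs-Shannon entropy of the binned chi distributions, averaged over the
#' chi angles of the residue:
#' \deqn{S_{SC} = -\frac{1}{N_\chi} \sum_\chi \sum_k P_\chi(k)\ln P_\chi(k)}
#' with the convention 0 ln 0 = 0 and the Boltzmann constant set to 1, so
#' S_SC is dimensionless and bounded by ln(36) for 10-degree bins. An
#' experimental joint mode (`joint = TRUE`) instead bins the chi angles
#' jointly and normalizes the joint entropy by N_chi.
#'
#' @param histograms a [weighted_dihedral_histogram()] or list of them, one
#'   per chi angle (marginal mode). For joint mode pass raw `angles`
#'   (n x N_chi matrix) and `weights` instead.
#' @param n_chi number of chi angles; default `length(histograms)`.
#' @param angles,weights,bin_width used only when `joint = TRUE`.
#' @param joint compute the joint-distribution entropy (experimental).
#' @return Scalar dimensionless entropy.
#' @export
residue_entropy <- function(histograms = NULL, n_chi = NULL,
                            angles = NULL, weights = NULL, bin_width = 10,
                            joint = FALSE) {
  if (joint) {
    stopifnot(is.matrix(angles))
    n <- nrow(angles)
    if (is.null(weights)) weights <- rep(1 / n, n)
    weights <- weights / sum(weights)
    edges <- seq(-180, 180, by = bin_width)
    key <- apply(angles, 2, function(a) {
      k <- findInterval(wrap_angle(a), edges, left.open = TRUE,
                        rightmost.closed = TRUE)
      pmax(k, 1L)
    })
    id <- apply(matrix(key, nrow = n), 1, paste, collapse = ":")
    p <- tapply(weights, id, sum)
    p <- p[p > 0]
    return(-sum(p * log(p)) / ncol(angles))
  }
  if (inherits(histograms, "dihedral_histogram"))
    histograms <- list(histograms)
  if (!length(histograms)) stop("empty histogram list")
  if (is.null(n_chi)) n_chi <- length(histograms)
  per_chi <- vapply(histograms, function(h) {
    p <- h$probs[h$probs > 0]
    if (!length(p)) stop("empty histogram")
    -sum(p * log(p))
  }, numeric(1))
  sum(per_chi) / n_chi
}

#' Per-state side-chain entropy profile
#'
#' Computes S_SC for every residue of an ensemble from its chi-angle series
#' and a weight vector (uniform = the raw prior ensemble; optimized weights
#' = the experimentally reweighted ensemble), applying the eligibility
#' rules of [eligible_residues()]. Residues with fewer than 100 effective
#' frames (Neff x n_frames) are flagged low-confidence but still computed.
#'
#' @param ensemble a [trajectory_ensemble()] with chi series.
#' @param weights per-frame weights (default: the ensemble's, usually
#'   uniform).
#' @param state label for the profile (e.g. `"Apo"`).
#' @param bin_width histogram bin width in degrees.
#' @return Object of class `"entropy_profile"`: data.frame `residues`
#'   (residue_id, resname, n_chi, s_sc, low_confidence), scalar `total`
#'   (sum over included residues), `state`, `excluded` report.
#' @export
entropy_profile <- function(ensemble, weights = NULL, state = "state",
                            bin_width = 10) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (is.null(ensemble$chi)) stop("ensemble carries no chi series")
  if (is.null(weights)) weights <- ensemble$weights
  weights <- weights / sum(weights)
  elig <- eligible_residues(ensemble$residue_names[ensemble$residues])
  n_eff_frames <- neff(weights) * ensemble$n_frames
  rows <- list(); excluded <- list()
  for (i in seq_along(ensemble$residues)) {
    id <- ensemble$residues[i]
    if (!elig$included[i]) {
      excluded[[id]] <- elig$reason[i]
      next
    }
    chim <- ensemble$chi[[id]]
    if (is.null(chim)) {
      excluded[[id]] <- "no chi series in ensemble"
      next
    }
    hists <- lapply(seq_len(ncol(chim)), function(j)
      weighted_dihedral_histogram(chim[, j], weights, bin_width))
    # n_chi from available series (may be fewer than the residue's full
    # complement when only e.g. chi3 was extracted)
    s <- residue_entropy(hists, n_chi = ncol(chim))
    rows[[id]] <- data.frame(residue_id = id, resname = elig$resname[i],
                             n_chi = ncol(chim), s_sc = s,
                             low_confidence = n_eff_frames < 100,
                             stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue_id = character(), resname = character(),
               n_chi = integer(), s_sc = numeric(),
               low_confidence = logical())
  rownames(res) <- NULL
  structure(list(residues = res, total = sum(res$s_sc), state = state,
                 excluded = excluded,
                 n_effective_frames = n_eff_frames),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile> state %s: %d residues, total S_SC = %.4f\n",
              x$state, nrow(x$residues), x$total))
  invisible(x)
}

#' Entropy convergence build-up curve
#'
#' Recomputes the binned-entropy estimate on growing trajectory prefixes
#' (with prefix weights renormalized), tracing how the estimate converges
#' with sampling. The final checkpoint equals the full-trajectory
#' [residue_entropy()] exactly.
#'
#' @param angles chi-angle series (degrees) for one dihedral.
#' @param weights per-frame weights (default uniform).
#' @param checkpoints increasing frame counts at which to evaluate; default
#'   20 points log-spaced up to the full length.
#' @param bin_width bin width in degrees.
#' @return data.frame with `n_frames` and `s_sc`.
#' @export
entropy_buildup <- function(angles, weights = NULL, checkpoints = NULL,
                            bin_width = 10) {
  n <- length(angles)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (is.null(checkpoints))
    checkpoints <- unique(round(exp(seq(log(10), log(n), length.out = 20))))
  checkpoints <- sort(unique(pmin(checkpoints, n)))
  if (any(diff(checkpoints) <= 0) || any(checkpoints < 1))
    stop("`checkpoints` must be increasing positive frame counts")
  s <- vapply(checkpoints, function(k) {
    h <- weighted_dihedral_histogram(angles[seq_len(k)],
                                     weights[seq_len(k)], bin_width)
    residue_entropy(list(h), n_chi = 1)
  }, numeric(1))
  data.frame(n_frames = checkpoints, s_sc = s)
}

#' Per-residue entropy differences between two states
#'
#' \eqn{\Delta S = S_b - S_a} per residue over the intersection of the two
#' residue sets (mismatches reported); positive values mean state `b` is
#' more disordered.
#'
#' @param profile_a,profile_b [entropy_profile()] objects.
#' @return List with `table` (residue_id, s_a, s_b, delta_s), `total_a`,
#'   `total_b`, `delta_total` (over the common residues), and `mismatch`.
#' @export
delta_entropy <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "entropy_profile"),
            inherits(profile_b, "entropy_profile"))
  a <- profile_a$residues; b <- profile_b$residues
  common <- intersect(a$residue_id, b$residue_id)
  if (!length(common)) stop("profiles share no residues")
  mismatch <- union(setdiff(a$residue_id, common),
                    setdiff(b$residue_id, common))
  ia <- match(common, a$residue_id); ib <- match(common, b$residue_id)
  tab <- data.frame(residue_id = common, s_a = a$s_sc[ia], s_b = b$s_sc[ib],
                    delta_s = b$s_sc[ib] - a$s_sc[ia],
                    stringsAsFactors = FALSE)
  list(table = tab, total_a = sum(tab$s_a), total_b = sum(tab$s_b),
       delta_total = sum(tab$delta_s), mismatch = mismatch,
       states = c(profile_a$state, profile_b$state))
}

#' Write entropy tables
#'
#' Per-residue entropy TSV (`residue_id`, `resname`, `n_chi`, `s_sc`,
#' `low_confidence`) or a delta-entropy TSV.
#'
#' @param profile an [entropy_profile()].
#' @param delta a [delta_entropy()] result.
#' @param path file path.
#' @export
write_entropy_table <- function(profile, path) {
  write.table(profile$residues, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_entropy_table
#' @export
write_delta_entropy_table <- function(delta, path) {
  write.table(delta$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
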