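#' Conformational ensemble container
#'
#' Frames x residues of unit methyl-axis vectors and side-chain chi angles,
#' plus per-frame weights (uniform prior by default). This is the columnar
#' core object consumed by the order-parameter, reweighting, and entropy
#' stages; trajectory-file ingestion is an adapter that produces one of
#' these.
#'
#' @param vectors named list (one per residue) of n_frames x 3 matrices of
#'   unit vectors.
#' @param chi named list (one per residue) of n_frames x n_chi matrices of
#'   dihedral angles in degrees, columns named `chi1`..`chi3`; may be NULL.
#' @param weights per-frame weights; default uniform. Normalized on input.
#' @param wells optional named list of per-frame well labels (integers),
#'   used for bookkeeping in synthetic fixtures.
#' @param residue_names optional named character vector of three-letter
#'   residue codes (defaults to `"MET"` for all residues).
#' @return Object of class `"trajectory_ensemble"`.
#' @export
trajectory_ensemble <- function(vectors, chi = NULL, weights = NULL,
                                wells = NULL, residue_names = NULL) {
  if (!is.list(vectors) || length(vectors) < 1L || is.null(names(vectors)))
    stop("`vectors` must be a non-empty named list")
  n_frames <- nrow(vectors[[1]])
  for (v in vectors) {
    if (!is.matrix(v) || ncol(v) != 3L || nrow(v) != n_frames)
      stop("all residues must have n_frames x 3 vector matrices")
    norms <- sqrt(rowSums(v^2))
    if (any(abs(norms - 1) > 1e-9))
      stop("bond vectors must be unit length (tolerance 1e-9)")
  }
  if (!is.null(chi)) {
    stopifnot(is.list(chi), length(chi) == length(vectors))
    for (m in chi) {
      if (!is.null(m) && nrow(m) != n_frames)
        stop("chi series must have n_frames rows")
    }
  }
  if (is.null(weights)) weights <- rep(1 / n_frames, n_frames)
  if (length(weights) != n_frames || any(weights < 0))
    stop("`weights` must be length n_frames and non-negative")
  s <- sum(weights)
  if (s <= 0) stop("`weights` must not be all zero")
  weights <- weights / s
  ids <- names(vectors)
  if (is.null(residue_names)) residue_names <- setNames(rep("MET", length(ids)), ids)
  structure(list(n_frames = n_frames, residues = ids, vectors = vectors,
                 chi = chi, weights = weights, wells = wells,
                 residue_names = residue_names),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d frames, %d residues (%s)\n",
              x$n_frames, length(x$residues),
              paste(head(x$residues, 5), collapse = ", ")))
  invisible(x)
}

#' Read and write columnar ensemble tables
#'
#' TSV schema: `frame`, `residue_id`, `x`, `y`, `z`, and optional
#' `chi1`..`chi3` columns in degrees. Round-trips a
#' [trajectory_ensemble()] (weights are stored separately, see
#' [write_weights()]).
#'
#' @param ensemble a [trajectory_ensemble()].
#' @param path file path.
#' @return `read_ensemble_table` returns a [trajectory_ensemble()];
#'   `write_ensemble_table` returns `path` invisibly.
#' @export
write_ensemble_table <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  rows <- lapply(ensemble$residues, function(id) {
    d <- data.frame(frame = seq_len(ensemble$n_frames), residue_id = id,
                    ensemble$vectors[[id]])
    names(d)[3:5] <- c("x", "y", "z")
    if (!is.null(ensemble$chi) && !is.null(ensemble$chi[[id]]))
      d <- cbind(d, as.data.frame(ensemble$chi[[id]]))
    d
  })
  tab <- do.call(rbind, rows)
  write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_table
#' @export
read_ensemble_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("frame", "residue_id", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("ensemble table must have columns: ", paste(need, collapse = ", "))
  chi_cols <- grep("^chi[123]$", names(tab), value = TRUE)
  ids <- unique(tab$residue_id)
  vectors <- list(); chis <- if (length(chi_cols)) list() else NULL
  for (id in ids) {
    sub <- tab[tab$residue_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    v <- as.matrix(sub[, c("x", "y", "z")])
    # re-normalize against text round-off
    v <- v / sqrt(rowSums(v^2))
    dimnames(v) <- list(NULL, c("x", "y", "z"))
    vectors[[id]] <- v
    if (!is.null(chis))
      chis[[id]] <- as.matrix(sub[, chi_cols, drop = FALSE])
  }
  trajectory_ensemble(vectors = vectors, chi = chis)
}

#' Read and write per-frame weight tables
#'
#' TSV schema: `frame`, `weight`.
#'
#' @param weights numeric vector of per-frame weights.
#' @param path file path.
#' @export
write_weights <- function(weights, path) {
  write.table(data.frame(frame = seq_along(weights),
                         weight = format(weights, digits = 17,
                                         scientific = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tab <- read.delim(path)
  tab$weight[order(tab$frame)]
}

#' Read and write reweighting target tables
#'
#' TSV schema: `residue_id`, `o2_mean`, `o2_sd`, optional `state`.
#'
#' @param targets data.frame with the schema above.
#' @param path file path.
#' @export
write_targets <- function(targets, path) {
  write.table(targets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue_id", "o2_mean", "o2_sd")
  if (!all(need %in% names(tab)))
    stop("targets table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Read and write intensity tables for relaxation fitting
#'
#' TSV/CSV schema: `peak_id`, `coherence` (`SQ`|`3Q`), `delay_s`,
#' `intensity`. One file can hold many peaks; [read_intensity_table()]
#' returns a named list of per-peak `list(sq =, tq =)` curve pairs.
#'
#' @param curves list of [decay_curve()] objects (any nesting; flattened).
#' @param path file path; `.csv` extension switches to comma separation.
#' @export
write_intensity_table <- function(curves, path) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "decay_curve")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
    invisible(NULL)
  }
  collect(curves)
  rows <- lapply(flat, function(cv)
    data.frame(peak_id = cv$peak_id, coherence = cv$coherence,
               delay_s = cv$delays, intensity = cv$intensities))
  tab <- do.call(rbind, rows)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(format(tab, digits = 17, trim = TRUE),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_table
#' @export
read_intensity_table <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("peak_id", "coherence", "delay_s", "intensity")
  if (!all(need %in% names(tab)))
    stop("intensity table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(tab$peak_id)) {
    sub <- tab[tab$peak_id == id, , drop = FALSE]
    pair <- list()
    for (coh in unique(sub$coherence)) {
      s2 <- sub[sub$coherence == coh, , drop = FALSE]
      s2 <- s2[order(s2$delay_s), , drop = FALSE]
      cv <- decay_curve(id, coh, s2$delay_s, s2$intensity)
      pair[[if (coh == "SQ") "sq" else "tq"]] <- cv
    }
    out[[id]] <- pair
  }
  out
}
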