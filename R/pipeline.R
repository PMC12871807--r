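#' Default demo configuration
#'
#' Returns the configuration tree used by the bundled demonstration
#' pipeline: a small synthetic study with a rotamer-jump ensemble, decay
#' curves, SAXS-derived tumbling, reweighting and entropy maps. Values can
#' be overridden by a YAML file with the same structure (see
#' [run_all()]).
#'
#' @return Nested list of stage parameters.
#' @export
demo_config <- function() {
  list(
    seed = 42L,
    states = list(prior = "prior", reweighted = "reweighted"),
    stages = list(simulate = TRUE, fit_relaxation = TRUE,
                  convert_o2 = TRUE, orderparams = TRUE,
                  reweight = TRUE, entropy = TRUE),
    simulate = list(
      wells = c(60, 180, -60),
      prior_populations = c(1, 1, 1) / 3,
      target_populations = c(0.6, 0.2, 0.2),
      libration_sd = 10, theta_bond = 109.47,
      exchange_prob = 0.2,
      n_frames = 2000L, n_residues = 3L,
      decay = list(eta = 30, delta = 5, amplitude = 1,
                   rates = c(40, 120), fractions = c(0.5, 0.5),
                   delays_s = seq(0.4e-3, 10e-3, length.out = 7),
                   noise_sd = 0.02)),
    relaxation = list(n_exp = 2L, chains = 2L, n_draws = 400L,
                      warmup = 600L),
    saxs = list(rg = 37.85, rg_sd = 0.4, rg_unit = "angstrom",
                viscosity_cP = 1.099, temperature_K = 298.15,
                tau_samples = 1000L),
    orderparams = list(max_lag = 200L),
    reweight = list(theta_grid = 10^seq(-2, 4, length.out = 13),
                    target_sd = 0.02),
    entropy = list(bin_width = 10))
}

#' Validate a pipeline configuration
#'
#' Schema and sanity checks: required fields, unit flags (an Rg quoted in
#' nanometres at tens of nm implies an implausibly large particle for a
#' receptor-micelle system), probability normalization, and cross-stage
#' consistency. Problems are returned as a report, not raised.
#'
#' @param config configuration list (or path to a YAML file).
#' @return data.frame with columns `level` (`"error"`/`"warning"`),
#'   `field`, `message`; zero rows means a clean configuration.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  rep_rows <- list()
  note <- function(level, field, message)
    rep_rows[[length(rep_rows) + 1L]] <<-
      data.frame(level = level, field = field, message = message)
  if (is.null(config$seed)) note("error", "seed", "missing seed")
  if (!is.null(config$saxs)) {
    unit <- config$saxs$rg_unit
    if (!is.null(unit) && unit %in% c("nm", "nanometer", "nanometre") &&
        isTRUE(config$saxs$rg > 10))
      note("warning", "saxs.rg",
           sprintf(paste0("Rg = %g nm implies a ~%.0f nm particle, ",
                          "implausible for a receptor-micelle system; ",
                          "Angstrom intended?"),
                   config$saxs$rg, config$saxs$rg))
    if (isTRUE(config$saxs$temperature_K < 150))
      note("warning", "saxs.temperature_K",
           "temperature below 150: Celsius given where Kelvin expected?")
  }
  if (!is.null(config$simulate)) {
    for (f in c("prior_populations", "target_populations")) {
      p <- config$simulate[[f]]
      if (!is.null(p) && abs(sum(p) - 1) > 1e-6)
        note("error", paste0("simulate.", f), "populations must sum to 1")
    }
    if (!is.null(config$simulate$target_populations) &&
        !is.null(config$simulate$wells) &&
        length(config$simulate$target_populations) !=
          length(config$simulate$wells))
      note("error", "simulate.target_populations",
           "length differs from wells")
  }
  if (!is.null(config$reweight) &&
      any(config$reweight$theta_grid < 0))
    note("error", "reweight.theta_grid", "theta must be >= 0")
  if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(level = character(), field = character(),
               message = character())
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet)
    message(format(Sys.time(), "[%H:%M:%S] "), stage, ": ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes the stages end-to-end on one configuration: simulate (optional)
#' -> fit-relaxation -> estimate-tauc/convert-o2 -> ensemble order
#' parameters -> reweight (with L-curve selection) -> entropy -> entropy
#' differences. Every stage writes a round-trippable TSV under `out_dir`
#' and the run closes with a JSON manifest recording the configuration,
#' seeds, per-stage outputs and their checksums. Identical configuration
#' and seeds reproduce every output byte-for-byte.
#'
#' @param config configuration list (see [demo_config()]) or path to a
#'   YAML file with the same structure; partial configs are completed with
#'   the demo defaults.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest_path`.
#' @export
run_all <- function(config = demo_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(demo_config(), config)
  report <- validate_config(config)
  if (any(report$level == "error"))
    stop("invalid configuration:\n",
         paste(sprintf("- %s: %s", report$field, report$message),
               collapse = "\n"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  outputs <- character()
  results <- list(config = config)
  add_output <- function(path) outputs <<- c(outputs, path)

  ## --- simulate -------------------------------------------------------
  if (isTRUE(config$stages$simulate)) {
    pipeline_log(quiet, "simulate", "rotamer-jump ensemble and decay curves")
    sim <- config$simulate
    # configs serialized through YAML may carry rounded probabilities
    sim$prior_populations <- sim$prior_populations /
      sum(sim$prior_populations)
    sim$target_populations <- sim$target_populations /
      sum(sim$target_populations)
    spec_prior <- rotamer_jump_spec(
      well_angles = sim$wells, populations = sim$prior_populations,
      exchange_prob = sim$exchange_prob, libration_sd = sim$libration_sd,
      theta_bond = sim$theta_bond, n_frames = sim$n_frames, seed = seed)
    fixture <- simulate_weighted_ensemble(
      spec_prior, sim$target_populations, n_residues = sim$n_residues,
      seed = seed, target_sd = config$reweight$target_sd)
    dc <- sim$decay
    spec_decay <- decay_curve_spec(
      eta = dc$eta, delta = dc$delta, amplitude = dc$amplitude,
      rates = dc$rates, fractions = dc$fractions, delays = dc$delays_s,
      noise_sd_sq = dc$noise_sd, noise_sd_3q = dc$noise_sd,
      seed = seed + 1L, peak_id = "demo_peak")
    curves <- simulate_decay_curves(spec_decay)
    add_output(write_ensemble_table(fixture$ensemble,
                                    file.path(out_dir, "ensemble.tsv")))
    add_output(write_targets(fixture$targets,
                             file.path(out_dir, "targets.tsv")))
    add_output(write_intensity_table(curves,
                                     file.path(out_dir, "intensities.tsv")))
    results$fixture <- fixture
    results$curves <- curves
  } else {
    stop("running without the simulate stage requires bundled inputs; ",
         "provide them via a custom driver")
  }

  ## --- fit-relaxation -------------------------------------------------
  if (isTRUE(config$stages$fit_relaxation)) {
    pipeline_log(quiet, "fit-relaxation", "simultaneous Bayesian fit")
    rl <- config$relaxation
    fit <- fit_simultaneous_bayes(results$curves$sq, results$curves$tq,
                                  n_exp = rl$n_exp, seed = seed + 2L,
                                  chains = rl$chains,
                                  n_draws = rl$n_draws,
                                  warmup = rl$warmup)
    add_output(write_fit_summary(list(fit),
                                 file.path(out_dir, "fit_summary.tsv")))
    results$fit <- fit
  }

  ## --- estimate-tauc / convert-o2 --------------------------------------
  if (isTRUE(config$stages$convert_o2) && !is.null(results$fit)) {
    pipeline_log(quiet, "convert-o2", "tau_c and O2axis from eta posterior")
    sx <- config$saxs
    rg <- sx$rg
    if (!is.null(sx$rg_unit) && sx$rg_unit %in% c("nm", "nanometer"))
      rg <- rg * 10
    tumbling <- tau_c_from_rg(rg, sx$rg_sd, sx$viscosity_cP,
                              sx$temperature_K,
                              n_samples = sx$tau_samples,
                              seed = seed + 3L)
    o2_nmr <- o2_from_eta(results$fit, tumbling, n_samples = 2000L,
                          seed = seed + 4L, state = "demo")
    add_output(write_o2_table(list(o2_nmr),
                              file.path(out_dir, "o2_nmr.tsv")))
    results$tumbling <- tumbling
    results$o2_nmr <- o2_nmr
  }

  ## --- ensemble order parameters ---------------------------------------
  if (isTRUE(config$stages$orderparams)) {
    pipeline_log(quiet, "md-orderparams", "tensor O2 and TCF plateaus")
    ens <- results$fixture$ensemble
    max_lag <- min(config$orderparams$max_lag, floor(ens$n_frames / 2) - 1L)
    op_rows <- lapply(ens$residues, function(id) {
      tcf <- internal_tcf(ens$vectors[[id]], max_lag = max_lag)
      data.frame(residue_id = id, state = "demo", source = "ensemble",
                 o2_tensor = o2_tensor(ens$vectors[[id]]),
                 o2_tcf = tcf_plateau(tcf))
    })
    op <- do.call(rbind, op_rows)
    write.table(op, file.path(out_dir, "o2_ensemble.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "o2_ensemble.tsv"))
    results$o2_ensemble <- op
  }

  ## --- reweight --------------------------------------------------------
  selection_note <- NULL
  weights <- NULL
  if (isTRUE(config$stages$reweight)) {
    pipeline_log(quiet, "reweight", "L-curve scan over theta")
    grid <- config$reweight$theta_grid
    lcurve <- l_curve_scan(results$fixture$ensemble,
                           results$fixture$targets, grid)
    add_output(write_lcurve(lcurve, file.path(out_dir, "lcurve.tsv")))
    if (length(grid) >= 5) {
      sel <- select_theta_elbow(lcurve)
      selection_note <- sprintf("theta = %g (%s)", sel$theta, sel$flag)
      theta_star <- sel$theta
    } else {
      selection_note <- "no elbow selection (grid too small)"
      theta_star <- grid[which.min(abs(grid - median(grid)))]
    }
    final <- optimize_weights(results$fixture$ensemble,
                              results$fixture$targets, theta_star)
    weights <- final$weights
    add_output(write_weights(weights, file.path(out_dir, "weights.tsv")))
    results$lcurve <- lcurve
    results$reweight <- final
  }

  ## --- entropy ---------------------------------------------------------
  if (isTRUE(config$stages$entropy)) {
    pipeline_log(quiet, "entropy", "side-chain entropy profiles")
    ens <- results$fixture$ensemble
    if (is.null(weights)) {
      pipeline_log(quiet, "entropy",
                   "no reweighting output: falling back to uniform weights")
      weights <- ens$weights
    }
    prof_prior <- entropy_profile(ens, state = config$states$prior,
                                  bin_width = config$entropy$bin_width)
    prof_rw <- entropy_profile(ens, weights = weights,
                               state = config$states$reweighted,
                               bin_width = config$entropy$bin_width)
    dS <- delta_entropy(prof_prior, prof_rw)
    add_output(write_entropy_table(prof_prior,
                                   file.path(out_dir, "entropy_prior.tsv")))
    add_output(write_entropy_table(prof_rw,
                                   file.path(out_dir,
                                             "entropy_reweighted.tsv")))
    add_output(write_delta_entropy_table(dS,
                                         file.path(out_dir,
                                                   "delta_entropy.tsv")))
    results$entropy <- list(prior = prof_prior, reweighted = prof_rw,
                            delta = dS)
  }

  ## --- manifest --------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("methylscape")),
    seed = seed,
    config = config,
    theta_selection = if (is.null(selection_note)) "stage skipped"
      else selection_note,
    outputs = lapply(setNames(outputs, basename(outputs)), function(p)
      list(path = basename(p),
           md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest_path <- manifest_path
  pipeline_log(quiet, "done", "manifest at ", manifest_path)
  invisible(results)
}
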