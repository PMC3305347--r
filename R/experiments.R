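#' Default experiment configuration
#'
#' Returns the study conditions used by the scripted experiments: a
#' 96-channel synthetic odor set (two highly similar pairs plus four
#' dissimilar background odors), K = 8 connections per granule cell,
#' inhibitory weight 0.02, spontaneous activity 0.1, resilience threshold
#' 0.15, survival threshold 0.15, sigmoid steepness 50, influx 40 cells per
#' step, and 800 evolution steps. Any field can be overridden.
#'
#' @param ... Named overrides of the default fields.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    n_channels = 96L, n_background = 4L, n_similar_pairs = 2L,
    focus_width = 0.4, pair_contrast = 0.12, amplitude = 1,
    connections = 8L, inh_weight = 0.02, spontaneous = 0.1,
    resilience_threshold = 0.15, survival_threshold = 0.15,
    steepness = 50, influx = 40L, n_steps = 800L, record_every = 10L,
    seed = 1L, n_seeds = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_steps >= 1, cfg$n_seeds >= 1, cfg$seed == round(cfg$seed))
  class(cfg) <- "experiment_config"
  cfg
}

config_params <- function(cfg) {
  survival_params(cfg$resilience_threshold, cfg$survival_threshold,
                  cfg$steepness, cfg$influx, connections = cfg$connections,
                  inh_weight = cfg$inh_weight, spontaneous = cfg$spontaneous)
}

config_ensemble <- function(cfg) {
  generate_odor_set(n_channels = cfg$n_channels,
                    n_background = cfg$n_background,
                    n_similar_pairs = cfg$n_similar_pairs,
                    width = cfg$focus_width, amplitude = cfg$amplitude,
                    pair_contrast = cfg$pair_contrast)
}

config_network <- function(cfg) {
  new_network(cfg$n_channels, connections = cfg$connections,
              inh_weight = cfg$inh_weight, spontaneous = cfg$spontaneous)
}

# seeds for multi-run averages: consecutive from the base seed
config_seeds <- function(cfg, n = cfg$n_seeds) cfg$seed + seq_len(n) - 1L

#' Decorrelation of a synthetic odor ensemble
#'
#' Evolves a network from the empty state on the configured ensemble and
#' reports input and output correlation matrices, the turnover trajectory,
#' and plateau statistics. The central readout is the within-pair
#' correlation of the similar pairs before versus after training.
#'
#' @param config An [experiment_config()].
#' @return A report list (class `bulb_report`) with elements `input`,
#'   `output` ([correlation_matrix()] reports), `trajectory`, `plateau`,
#'   `network`, and the resolved `config`.
#' @export
run_decorrelation <- function(config = experiment_config()) {
  set.seed(config$seed)
  ens <- config_ensemble(config)
  traj <- evolve(config_network(config), ens, config$n_steps,
                 config_params(config), record_every = config$record_every)
  structure(list(
    experiment = "decorrelation",
    input = correlation_matrix(ens),
    output = correlation_matrix(traj$steady),
    trajectory = traj$trajectory,
    plateau = detect_plateau(traj),
    network = traj$network, ensemble = ens,
    config = config, seed = config$seed), class = "bulb_report")
}

#' @export
print.bulb_report <- function(x, ...) {
  cat(sprintf("<bulb_report> experiment '%s' (seed %d)\n", x$experiment, x$seed))
  invisible(x)
}

#' Robustness of decorrelation to imperfect reciprocity
#'
#' Three perturbation arms on the synthetic odor set. (i) Rewiring: a
#' fraction of each granule cell's inhibitory connections is redirected to
#' random mitral cells; with all connections rewired the inhibition becomes
#' statistically uniform across channels and — Pearson correlations being
#' invariant to a common suppression — the output correlations return to
#' the input level. This arm runs in the weak-coupling regime (inhibitory
#' weight 0.005, populations of several thousand cells, twice the
#' configured number of steps so that selection has enough cell
#' generations): with many weakly weighted synapses the rewired effective
#' connectivity concentrates around its uniform mean and the linearized
#' activity dynamics remain stable across the entire sweep, which is the
#' regime in which the linear coupling is valid. (ii) Heterogeneous
#' inhibitory weights (two-point spread up to `delta = w`), reporting the
#' asymmetry of the effective connectivity alongside the correlations.
#' (iii) Rebalancing self- versus lateral inhibition at fixed row sums
#' (gamma sweep).
#'
#' @param config An [experiment_config()]; `n_seeds` controls averaging.
#' @param arms Subset of `c("rewire", "weights", "gamma")`.
#' @param rewire_fractions,gammas Sweep grids.
#' @return A `bulb_report` with one data frame per arm (`rewire`, `weights`,
#'   `gamma`; sweep value, seed, pair and mean correlations) plus the input
#'   correlations.
#' @export
run_reciprocity_study <- function(config = experiment_config(
                                    n_steps = 400L, n_seeds = 3L),
                                  arms = c("rewire", "weights", "gamma"),
                                  rewire_fractions = c(0, 0.25, 0.5, 0.75, 1),
                                  gammas = c(0.5, 1, 1.5)) {
  arms <- match.arg(arms, several.ok = TRUE)
  set.seed(config$seed)
  ens <- config_ensemble(config)
  params <- config_params(config)
  pair_cols <- function(cm) c(pair1 = cm$matrix[1, 2], pair2 = cm$matrix[3, 4],
                              mean = cm$mean)
  one_run <- function(seed, ...) {
    set.seed(seed)
    traj <- evolve(config_network(config), ens, config$n_steps, params,
                   record_every = config$n_steps, ...)
    out <- pair_cols(correlation_matrix(traj$steady))
    c(out, asymmetry = asymmetry_ratio(effective_connectivity(traj$network)))
  }
  report <- list(experiment = "reciprocity", config = config,
                 seed = config$seed, input = correlation_matrix(ens))
  if ("rewire" %in% arms) {
    rw_w <- 0.005
    rw_params <- survival_params(config$resilience_threshold,
                                 config$survival_threshold, config$steepness,
                                 config$influx, connections = config$connections,
                                 inh_weight = rw_w,
                                 spontaneous = config$spontaneous)
    rw_steps <- 2L * config$n_steps
    one_rw <- function(fraction, seed) {
      set.seed(seed)
      net <- new_network(config$n_channels, connections = config$connections,
                         inh_weight = rw_w, spontaneous = config$spontaneous)
      traj <- evolve(net, ens, rw_steps, rw_params,
                     record_every = rw_steps, rewire_fraction = fraction)
      pair_cols(correlation_matrix(traj$steady))
    }
    grid <- expand.grid(fraction = rewire_fractions,
                        seed = config_seeds(config))
    res <- t(mapply(one_rw, grid$fraction, grid$seed))
    report$rewire <- cbind(grid, res)
  }
  if ("weights" %in% arms) {
    grid <- expand.grid(delta = c(0, config$inh_weight / 2, config$inh_weight),
                        seed = config_seeds(config))
    res <- t(mapply(function(d, s)
      one_run(s, weight_mode = "two_point", weight_delta = d),
      grid$delta, grid$seed))
    report$weights <- cbind(grid, res)
  }
  if ("gamma" %in% arms) {
    grid <- expand.grid(gamma = gammas, seed = config_seeds(config))
    res <- t(mapply(function(g, s) one_run(s, gamma = g),
                    grid$gamma, grid$seed))
    report$gamma <- cbind(grid, res)
  }
  class(report) <- "bulb_report"
  report
}

#' Age-dependent response of marked granule cells to novel versus familiar odors
#'
#' Trains a network on all but the last odor of the configured ensemble (the
#' held-out odor is "novel"), marks the granule cells integrated during a
#' window at the plateau, continues the evolution, and tracks the fraction of
#' surviving marked cells whose activity exceeds the IEG proxy threshold
#' `theta_IEG` for each stimulus. The readout per stimulus is the ratio
#' `rho = fraction(final) / fraction(end of marking)`; cells responding to
#' the novel odor receive little drive from the training ensemble, so their
#' survival is poor and `rho(novel) < rho(familiar)` on average.
#'
#' @param config An [experiment_config()]; `n_seeds` controls averaging.
#' @param theta_IEG Response threshold (defaults to the resilience
#'   threshold, the regime in which novelty detection is expressed).
#' @param mark_duration Length of the marking window (steps).
#' @param follow_steps Steps simulated after the marking window.
#' @param theta_grid Grid of thresholds for the response-fraction curve
#'   evaluated at the end of marking.
#' @return A `bulb_report` with `rho` (per seed: novel and mean familiar
#'   rho), `fraction_curve` (response fraction vs theta_IEG, averaged over
#'   seeds) and the resolved config.
#' @export
run_novelty <- function(config = experiment_config(n_steps = 250L,
                                                   n_seeds = 8L),
                        theta_IEG = config$resilience_threshold,
                        mark_duration = 10L, follow_steps = 60L,
                        theta_grid = seq(0, 6, by = 0.5) *
                          max(config$resilience_threshold, 0.05)) {
  set.seed(config$seed)
  full <- config_ensemble(config)
  n_stim <- ncol(full$patterns)
  familiar <- stimulus_ensemble(full$patterns[, -n_stim, drop = FALSE])
  params <- config_params(config)
  one_seed <- function(seed) {
    set.seed(seed)
    net <- config_network(config)
    mark_from <- config$n_steps - mark_duration + 1L
    traj <- evolve(net, familiar, config$n_steps, params,
                   record_every = config$n_steps,
                   mark_window = c(mark_from, config$n_steps))
    st0 <- solve_steady_state(traj$network, full)
    frac0 <- response_fraction(st0, traj$network, theta_IEG)
    curve0 <- vapply(theta_grid, function(th)
      mean(response_fraction(st0, traj$network, th)), numeric(1))
    traj2 <- evolve(traj$network, familiar, follow_steps, params,
                    record_every = follow_steps)
    st1 <- solve_steady_state(traj2$network, full)
    frac1 <- response_fraction(st1, traj2$network, theta_IEG)
    rho <- frac1 / frac0
    list(rho_novel = rho[n_stim], rho_familiar = mean(rho[-n_stim]),
         frac0 = frac0, frac1 = frac1, curve = curve0)
  }
  seeds <- config_seeds(config)
  runs <- lapply(seeds, one_seed)
  rho <- data.frame(seed = seeds,
                    novel = vapply(runs, `[[`, numeric(1), "rho_novel"),
                    familiar = vapply(runs, `[[`, numeric(1), "rho_familiar"))
  curve <- colMeans(do.call(rbind, lapply(runs, `[[`, "curve")))
  structure(list(experiment = "novelty", rho = rho,
                 fraction_curve = data.frame(theta_IEG = theta_grid,
                                             response_fraction = curve),
                 theta_IEG = theta_IEG, runs = runs,
                 config = config, seed = config$seed),
            class = "bulb_report")
}

#' Perceptual learning through odor enrichment
#'
#' A network is first trained on a background ensemble; the correlation of a
#' held-out pair of highly similar test odors is then followed while the
#' environment is enriched. Three conditions are compared: enrichment with
#' the related odors (the test pair itself), with unrelated odors (a similar
#' pair on disjoint glomerular support), and with related odors but with the
#' granule-cell influx stopped at enrichment onset (no neurogenesis).
#' Relatedness is quantified by the Pearson overlap between enrichment and
#' test patterns and reported alongside the results.
#'
#' @param config An [experiment_config()].
#' @param pre_steps Steps of background-only training.
#' @param post_steps Steps after enrichment onset.
#' @return A `bulb_report` with `timecourse` (probe-pair correlation vs step
#'   per condition), `final` (final probe correlations), `relatedness`, and
#'   the resolved config.
#' @export
run_perceptual_learning <- function(config = experiment_config(),
                                    pre_steps = 400L, post_steps = 400L) {
  set.seed(config$seed)
  full <- config_ensemble(config)
  test_pair <- stimulus_ensemble(full$patterns[, 1:2, drop = FALSE])
  unrelated <- stimulus_ensemble(full$patterns[, 3:4, drop = FALSE])
  background <- stimulus_ensemble(full$patterns[, -(1:4), drop = FALSE])
  params <- config_params(config)
  relatedness <- c(
    related = suppressWarnings(pearson(full$patterns[, 1L], full$patterns[, 1L])),
    unrelated = suppressWarnings(pearson(full$patterns[, 1L], full$patterns[, 3L])))
  enrich_ens <- function(extra)
    stimulus_ensemble(cbind(background$patterns, extra$patterns))
  conditions <- list(
    related = list(ensemble = enrich_ens(test_pair), influx = NULL),
    unrelated = list(ensemble = enrich_ens(unrelated), influx = NULL),
    related_no_neurogenesis = list(ensemble = enrich_ens(test_pair), influx = 0L))
  timecourse <- list(); final <- numeric(0)
  for (nm in names(conditions)) {
    set.seed(config$seed)
    phases <- list(
      list(from = 1L, ensemble = background),
      c(list(from = pre_steps + 1L,
             ensemble = conditions[[nm]]$ensemble),
        if (!is.null(conditions[[nm]]$influx))
          list(influx = conditions[[nm]]$influx)))
    traj <- evolve(config_network(config), phases, pre_steps + post_steps,
                   params, record_every = config$record_every,
                   probe = test_pair)
    timecourse[[nm]] <- traj$trajectory[, c("step", "probe_correlation")]
    final[nm] <- utils::tail(traj$trajectory$probe_correlation, 1L)
  }
  structure(list(experiment = "perceptual_learning", timecourse = timecourse,
                 final = final, enrichment_onset = pre_steps,
                 relatedness = relatedness, config = config,
                 seed = config$seed), class = "bulb_report")
}

#' Alternating versus mixture enrichment protocols
#'
#' Compares how well the network learns to decorrelate highly similar
#' mixtures of two dissimilar components X and Y after enrichment with (a)
#' the pure components presented as separate stimuli within each assessment
#' interval ("alternating") or (b) their 50:50 mixture ("mixture"). Test
#' stimuli are the 35:65 and 65:35 mixtures; the readout is their output
#' correlation after training, over `config$n_seeds` consecutive seeds, for
#' the configured K and for the single-connection control (K = 1), for which
#' granule cells provide no lateral inhibition and the protocols should not
#' differ. Quadrant sums of the effective connectivity over the X/Y supports
#' quantify the cross-component ("mixed" granule cell) inhibition.
#'
#' @param config An [experiment_config()].
#' @param test_fractions Mixture fractions of component X for the test pair.
#' @param pre_steps,post_steps Background-only and enrichment phases.
#' @param connection_counts K values to compare (default `c(config, 1)`).
#' @return A `bulb_report` with `results` (per K, protocol, seed: final test
#'   correlation and cross-quadrant sum) and `input_correlation` of the test
#'   pair.
#' @export
run_enrichment_protocols <- function(config = experiment_config(n_steps = 600L,
                                                                n_seeds = 8L),
                                     test_fractions = c(0.35, 0.65),
                                     pre_steps = 250L, post_steps = 350L,
                                     connection_counts = c(config$connections, 1L)) {
  set.seed(config$seed)
  full <- config_ensemble(config)
  # components: two dissimilar single odors with disjoint focal support
  X <- glomerular_pattern(full$patterns[, 1L], "component_X")
  Y <- glomerular_pattern(full$patterns[, 3L], "component_Y")
  background <- stimulus_ensemble(full$patterns[, -(1:4), drop = FALSE])
  test <- stimulus_ensemble(
    cbind(mix_patterns(list(X, Y), c(test_fractions[1L], 1 - test_fractions[1L]))$values,
          mix_patterns(list(X, Y), c(test_fractions[2L], 1 - test_fractions[2L]))$values),
    labels = c("test_mix_a", "test_mix_b"))
  support_X <- which(X$values > 0.1); support_Y <- which(Y$values > 0.1)
  # the mixture is presented at the full concentration of each component
  # (fractions 1:1), so every glomerular channel receives the same drive per
  # assessment interval under both protocols; the protocols then differ only
  # through the co-activation of the two components' channels
  ensembles <- list(
    alternating = make_enrichment_schedule(background, list(X, Y), "alternating"),
    mixture = make_enrichment_schedule(background, list(X, Y), "mixture",
                                       fractions = c(1, 1)))
  rows <- list()
  for (K in connection_counts) {
    params <- survival_params(config$resilience_threshold,
                              config$survival_threshold, config$steepness,
                              config$influx, connections = K,
                              inh_weight = config$inh_weight,
                              spontaneous = config$spontaneous)
    for (protocol in names(ensembles)) {
      for (seed in config_seeds(config)) {
        set.seed(seed)
        net <- new_network(config$n_channels, connections = K,
                           inh_weight = config$inh_weight,
                           spontaneous = config$spontaneous)
        phases <- list(list(from = 1L, ensemble = background),
                       list(from = pre_steps + 1L,
                            ensemble = ensembles[[protocol]]))
        traj <- evolve(net, phases, pre_steps + post_steps, params,
                       record_every = pre_steps + post_steps, probe = test)
        W <- effective_connectivity(traj$network)
        sub <- c(support_X, support_Y)
        qs <- quadrant_sums(W[sub, sub, drop = FALSE],
                            list(seq_along(support_X),
                                 length(support_X) + seq_along(support_Y)))
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, protocol = protocol, seed = seed,
          test_correlation = utils::tail(traj$trajectory$probe_correlation, 1L),
          cross_quadrant = qs[1L, 2L] + qs[2L, 1L],
          granule_count = n_granule_cells(traj$network))
      }
    }
  }
  structure(list(experiment = "enrichment_protocols",
                 results = do.call(rbind, rows),
                 input_correlation = suppressWarnings(
                   pearson(test$patterns[, 1L], test$patterns[, 2L])),
                 config = config, seed = config$seed), class = "bulb_report")
}

#' Mean-field phase-plane and threshold analysis
#'
#' Runs the analytical arm of the study on the symmetric four-stimulus
#' caricature: a scan of the resilience threshold (exact finite-steepness
#' fixed points and the within-pair output correlation of test stimuli of
#' the given similarity), the closed-form optimal threshold, the steep-limit
#' nullclines, and the alternating/mixture protocol comparison.
#'
#' @param influx,inh_weight,survival_threshold,steepness,spontaneous
#'   Mean-field parameters (see [population_params()]).
#' @param threshold_grid Grid of resilience thresholds to scan.
#' @param test_similarity Similarity of the test pair used for the
#'   correlation readout.
#' @return A `bulb_report` with `scan` (threshold, populations, correlation),
#'   `optimal` (closed form), `argmin` (scan minimum), `mixture`
#'   (protocol comparison) and `nullclines`.
#' @export
run_population_analysis <- function(influx = 2, inh_weight = 0.01,
                                    survival_threshold = 0.4,
                                    steepness = 2000, spontaneous = 0.1,
                                    threshold_grid = seq(0.01, 0.14, by = 0.01),
                                    test_similarity = 0.9) {
  pp_at <- function(th)
    symmetric4_population_params(influx = influx, inh_weight = inh_weight,
                                 resilience_threshold = th,
                                 survival_threshold = survival_threshold,
                                 steepness = steepness,
                                 spontaneous = spontaneous)
  scan <- do.call(rbind, lapply(threshold_grid, function(th) {
    fp <- fixed_point_symmetric4(pp_at(th), method = "exact")
    data.frame(threshold = th, coactive = fp$coactive,
               interfering = fp$interfering, regime = fp$regime,
               correlation = correlation_expansion(pp_at(th), fp$coactive,
                                                   fp$interfering,
                                                   similarity = test_similarity))
  }))
  pp_opt <- pp_at(threshold_grid[1L])
  opt <- optimal_threshold(pp_opt)
  fp_ref <- fixed_point_symmetric4(pp_opt, method = "closed_form")
  nc_grid <- seq(0.25, 1.25, length.out = 21) * max(fp_ref$coactive, 1)
  structure(list(experiment = "population_analysis", scan = scan,
                 optimal = opt,
                 argmin = scan$threshold[which.min(scan$correlation)],
                 mixture = mixture_comparison(pp_at(0.05), method = "exact"),
                 nullclines = nullclines_symmetric4(pp_at(0.05), nc_grid),
                 config = list(influx = influx, inh_weight = inh_weight,
                               survival_threshold = survival_threshold,
                               steepness = steepness,
                               spontaneous = spontaneous,
                               test_similarity = test_similarity),
                 seed = NA_integer_), class = "bulb_report")
}
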