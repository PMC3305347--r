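#' Survival and turnover parameters
#'
#' Collects every free parameter of the structural-plasticity loop: the
#' per-stimulus resilience threshold theta_R (activity below it contributes
#' nothing to resilience), the soft survival threshold theta_S on the summed
#' resilience, the steepness of the survival sigmoid, the influx of new
#' granule cells per evolution step, the connections per cell K, the
#' inhibitory weight w, and the spontaneous mitral activity s0.
#'
#' @param resilience_threshold theta_R >= 0.
#' @param survival_threshold theta_S >= 0.
#' @param steepness Sigmoid slope (> 0); large values approach a hard step at
#'   the survival threshold.
#' @param influx New granule cells per evolution step (integer >= 0).
#' @param connections Connections per granule cell K (>= 1).
#' @param inh_weight Inhibitory synaptic weight w (>= 0).
#' @param spontaneous Spontaneous mitral activity s0 (>= 0).
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(resilience_threshold, survival_threshold,
                            steepness, influx, connections = 8,
                            inh_weight = 0.01, spontaneous = 0.1) {
  stopifnot(resilience_threshold >= 0, survival_threshold >= 0,
            steepness > 0, influx >= 0, influx == round(influx),
            connections >= 1, inh_weight >= 0, spontaneous >= 0)
  structure(list(resilience_threshold = resilience_threshold,
                 survival_threshold = survival_threshold,
                 steepness = steepness, influx = as.integer(influx),
                 connections = as.integer(connections),
                 inh_weight = inh_weight, spontaneous = spontaneous),
            class = "survival_params")
}

#' Granule-cell resilience
#'
#' The survival statistic of a granule cell: its activity, thresholded at the
#' resilience threshold and summed over all stimuli of the ensemble,
#' `R = sum_mu max(g_mu - theta_R, 0)`. The rectifier makes the resilience a
#' concave function of the activity profile at fixed total activity, so cells
#' with a few strong responses (co-activity detectors) are more resilient than
#' cells with many intermediate responses (interfering connections).
#'
#' @param granule_activity Granule-by-stimulus activity matrix (or vector of
#'   per-stimulus activities for a single cell).
#' @param resilience_threshold theta_R.
#' @return A numeric vector, one nonnegative resilience per granule cell.
#' @export
resilience <- function(granule_activity, resilience_threshold) {
  if (is.null(dim(granule_activity)))
    granule_activity <- matrix(granule_activity, nrow = 1L)
  stopifnot(all(is.finite(granule_activity)), resilience_threshold >= 0)
  rowSums(pmax(granule_activity - resilience_threshold, 0))
}

#' Survival probability
#'
#' Sigmoidal (centered logistic) dependence of per-assessment survival on
#' resilience: `T(R) = 1 / (1 + exp(-steepness * (R - theta_S)))`. The
#' probability is 1/2 at the soft survival threshold and approaches a step
#' function as the steepness grows.
#'
#' @param resilience_value Resilience value(s) (>= 0).
#' @param params A [survival_params()] object.
#' @return Survival probabilities in `[0, 1]`.
#' @export
survival_probability <- function(resilience_value, params) {
  stats::plogis(params$steepness *
                  (resilience_value - params$survival_threshold))
}

#' One structural-plasticity step
#'
#' Adds `params$influx` new granule cells (each wired to K distinct random
#' mitral cells with reciprocal synapses), solves the steady state for the
#' current ensemble, computes every granule cell's resilience, and removes
#' each cell independently with probability `1 - T(R)`. Newly added cells are
#' assessed in the same step (they experience the full ensemble within the
#' assessment interval). Uses the current RNG state.
#'
#' @param net A `bulb_network`.
#' @param ensemble A [stimulus_ensemble()].
#' @param params A [survival_params()].
#' @param step Step index recorded on newborn cells.
#' @param influx Influx override (e.g. 0 after an influx cut); defaults to
#'   `params$influx`.
#' @param gamma Self-inhibition rescaling applied to the effective
#'   connectivity before the solve (see [rescale_self_inhibition()]).
#' @param rewire_fraction Fraction of each newborn cell's inhibitory targets
#'   redirected to random mitral cells (see [rewire()]).
#' @param weight_mode,weight_delta Weight heterogeneity applied to newborn
#'   cells (see [heterogenize_weights()]).
#' @param cohort Cohort tag for newborn cells.
#' @param coupling Steady-state coupling mode passed to
#'   [solve_steady_state()]; the rectified mode is required in regimes where
#'   the linear solve would produce strongly negative activities (e.g. fully
#'   rewired inhibition).
#' @return A list: `network` (after removal), `steady` (pre-removal steady
#'   state), `record` (one-row data frame: step, granule_count, removals,
#'   removal_rate, mean_resilience).
#' @export
evolution_step <- function(net, ensemble, params, step = NA_integer_,
                           influx = NULL, gamma = 1, rewire_fraction = 0,
                           weight_mode = NULL, weight_delta = 0,
                           cohort = NA_character_,
                           coupling = c("linear", "rectified")) {
  coupling <- match.arg(coupling)
  if (is.null(influx)) influx <- params$influx
  n_before <- n_granule_cells(net)
  if (influx > 0) {
    newborn <- new_network(net$M, net$K, net$w, net$spontaneous)
    newborn <- add_granule_cells(newborn, influx, step = step, cohort = cohort)
    if (rewire_fraction > 0) newborn <- rewire(newborn, rewire_fraction)
    if (!is.null(weight_mode) && weight_delta > 0)
      newborn <- heterogenize_weights(newborn, weight_mode, weight_delta)
    net$exc <- rbind(net$exc, newborn$exc)
    net$inh <- rbind(net$inh, newborn$inh)
    net$inh_w <- rbind(net$inh_w, newborn$inh_w)
    net$birth_step <- c(net$birth_step, newborn$birth_step)
    net$cohort <- c(net$cohort, newborn$cohort)
  }
  if (coupling == "linear") {
    W <- effective_connectivity(net)
    if (gamma != 1) W <- rescale_self_inhibition(W, gamma)
    steady <- solve_steady_state(net, ensemble, coupling = "linear", W = W)
  } else {
    if (gamma != 1)
      stop("self-inhibition rescaling requires linear coupling")
    steady <- solve_steady_state(net, ensemble, coupling = "rectified",
                                 tol = 1e-8, max_iter = 5e3)
  }
  G <- n_granule_cells(net)
  if (G > 0) {
    R <- resilience(steady$granule, params$resilience_threshold)
    p_survive <- survival_probability(R, params)
    keep <- stats::runif(G) < p_survive
    removals <- sum(!keep)
    net <- remove_granule_cells(net, keep)
    mean_res <- mean(R)
  } else {
    removals <- 0L
    mean_res <- NA_real_
  }
  record <- data.frame(step = step, granule_count = n_granule_cells(net),
                       removals = removals,
                       removal_rate = if (params$influx > 0)
                         removals / params$influx else NA_real_,
                       mean_resilience = mean_res)
  list(network = net, steady = steady, record = record)
}

#' Evolve a network under a stimulus schedule
#'
#' Runs the structural-plasticity loop for `n_steps` survival-assessment
#' intervals. The stimulus environment may change over time via `phases`:
#' a list of phases, each `list(from = <first step>, ensemble = <ensemble>,
#' influx = <optional override>)`. Supports starting from a network without
#' any granule cells, mid-run enrichment (a later phase with a larger
#' ensemble) and stopping the influx (`influx = 0` in a phase).
#'
#' @param net A `bulb_network` (possibly with zero granule cells).
#' @param phases A single [stimulus_ensemble()] or a list of phases as above
#'   (the first phase must start at step 1).
#' @param n_steps Number of evolution steps (>= 1).
#' @param params A [survival_params()].
#' @param record_every Record the trajectory every so many steps.
#' @param probe Optional [stimulus_ensemble()] of test stimuli that are
#'   solved and recorded at every recorded step but never drive survival.
#' @param track_pairs Stimulus index pairs (list of length-2 integer vectors)
#'   whose pairwise output correlation is recorded; `NULL` records all pairs
#'   of the active ensemble.
#' @param gamma,rewire_fraction,weight_mode,weight_delta,coupling Structural
#'   perturbations and coupling mode, as in [evolution_step()].
#' @param mark_window Optional integer range `c(first, last)`: cells born in
#'   these steps are tagged with cohort `"marked"` (see [response_fraction()]).
#' @return An object of class `bulb_trajectory`: `network` (final), `steady`
#'   (final steady state on the final ensemble), `trajectory` (data frame) and
#'   `phases`.
#' @export
evolve <- function(net, phases, n_steps, params, record_every = 1,
                   probe = NULL, track_pairs = NULL, gamma = 1,
                   rewire_fraction = 0, weight_mode = NULL, weight_delta = 0,
                   mark_window = NULL, coupling = c("linear", "rectified")) {
  coupling <- match.arg(coupling)
  stopifnot(n_steps >= 1)
  if (inherits(phases, "stimulus_ensemble"))
    phases <- list(list(from = 1L, ensemble = phases))
  if (length(phases) == 0L) stop("empty schedule")
  starts <- vapply(phases, function(p) as.integer(p$from), integer(1))
  if (starts[1L] != 1L) stop("first phase must start at step 1")
  records <- vector("list", n_steps)
  cors <- vector("list", n_steps)
  steady <- NULL
  for (step in seq_len(n_steps)) {
    ph <- phases[[max(which(starts <= step))]]
    influx <- if (!is.null(ph$influx)) ph$influx else params$influx
    cohort <- if (!is.null(mark_window) &&
                  step >= mark_window[1L] && step <= mark_window[2L])
      "marked" else NA_character_
    res <- evolution_step(net, ph$ensemble, params, step = step,
                          influx = influx, gamma = gamma,
                          rewire_fraction = rewire_fraction,
                          weight_mode = weight_mode,
                          weight_delta = weight_delta, cohort = cohort,
                          coupling = coupling)
    net <- res$network
    steady <- res$steady
    if (step %% record_every == 0 || step == n_steps) {
      records[[step]] <- res$record
      cors[[step]] <- .trajectory_correlations(net, res$steady, ph$ensemble,
                                               probe, track_pairs, gamma,
                                               coupling)
    }
  }
  keep <- !vapply(records, is.null, logical(1))
  traj <- do.call(rbind, records[keep])
  traj <- cbind(traj, .rbind_fill(cors[keep]))
  rownames(traj) <- NULL
  structure(list(network = net, steady = steady, trajectory = traj,
                 phases = phases, params = params),
            class = "bulb_trajectory")
}

# rbind data frames whose columns may differ (e.g. across schedule phases
# with different ensemble sizes), filling absent columns with NA
.rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(df) {
    for (nm in setdiff(cols, names(df))) df[[nm]] <- NA_real_
    df[cols]
  }))
}

.trajectory_correlations <- function(net, steady, ensemble, probe,
                                     track_pairs, gamma = 1,
                                     coupling = "linear") {
  m <- steady$mitral
  if (is.null(track_pairs)) {
    n <- ncol(m)
    track_pairs <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      track_pairs <- c(track_pairs, list(c(i, j)))
  }
  vals <- vapply(track_pairs, function(pr)
    suppressWarnings(pearson(m[, pr[1L]], m[, pr[2L]])), numeric(1))
  names(vals) <- vapply(track_pairs, function(pr)
    paste0("cor_", pr[1L], "_", pr[2L]), character(1))
  out <- as.data.frame(as.list(vals))
  out$mean_correlation <- mean(vals, na.rm = TRUE)
  if (!is.null(probe)) {
    ps <- if (coupling == "linear") {
      W <- effective_connectivity(net)
      if (gamma != 1) W <- rescale_self_inhibition(W, gamma)
      solve_steady_state(net, probe, W = W)
    } else {
      solve_steady_state(net, probe, coupling = "rectified",
                         tol = 1e-8, max_iter = 5e3)
    }
    out$probe_correlation <-
      suppressWarnings(pearson(ps$mitral[, 1L], ps$mitral[, 2L]))
  }
  out
}

#' @export
print.bulb_trajectory <- function(x, ...) {
  cat(sprintf("<bulb_trajectory> %d recorded steps, final granule count %d\n",
              nrow(x$trajectory), n_granule_cells(x$network)))
  invisible(x)
}

#' Detect a population plateau
#'
#' Trailing-window stationarity test on the granule count: fits a least-squares
#' slope over the last `window` recorded steps and compares the relative slope
#' (per step, normalized by the window mean) against `slope_tol`.
#'
#' @param traj A `bulb_trajectory`, an experiment report carrying a
#'   `trajectory` element, or the trajectory data frame itself.
#' @param window Number of trailing recorded steps (default half the record).
#' @param slope_tol Maximum |relative slope| per step to call a plateau.
#' @return A list: `plateau` (logical), `mean_count`, `slope`,
#'   `relative_slope`, `mean_removals`.
#' @export
detect_plateau <- function(traj, window = NULL, slope_tol = 5e-4) {
  df <- if (is.data.frame(traj)) traj
        else if (!is.null(traj$trajectory)) traj$trajectory
        else stop("no trajectory found")
  if (is.null(window)) window <- max(10L, nrow(df) %/% 2L)
  tail_df <- utils::tail(df, window)
  fit <- stats::lm(granule_count ~ step, data = tail_df)
  slope <- unname(stats::coef(fit)[2L])
  mean_count <- mean(tail_df$granule_count)
  rel <- if (mean_count > 0) slope / mean_count else 0
  list(plateau = abs(rel) <= slope_tol, mean_count = mean_count,
       slope = slope, relative_slope = rel,
       mean_removals = mean(tail_df$removals))
}

#' Mark the currently present granule cells born in a step window
#'
#' Tags, as cohort `"marked"`, the surviving granule cells whose birth step
#' falls inside `step_window`. (During [evolve()], the same effect is achieved
#' with `mark_window`, which tags the cells at birth.)
#'
#' @param net A `bulb_network`.
#' @param step_window Integer range `c(first, last)` of birth steps.
#' @export
mark_cohort <- function(net, step_window) {
  sel <- !is.na(net$birth_step) &
    net$birth_step >= step_window[1L] & net$birth_step <= step_window[2L]
  net$cohort[sel] <- "marked"
  net
}

#' Fraction of a marked cohort responding to a stimulus
#'
#' A granule cell "responds" to a stimulus if its steady-state activity
#' exceeds `theta_IEG` (a proxy for the activation threshold of immediate
#' early gene expression). The fraction is taken over the surviving members
#' of the cohort.
#'
#' @param steady A [solve_steady_state()] result for the network `net`.
#' @param net The `bulb_network` the steady state was computed for.
#' @param theta_IEG Response threshold.
#' @param stimulus Stimulus index (or label) to evaluate; `NULL` returns a
#'   vector over all stimuli.
#' @param cohort Cohort tag (default `"marked"`).
#' @return Response fraction(s) in `[0, 1]`.
#' @export
response_fraction <- function(steady, net, theta_IEG, stimulus = NULL,
                              cohort = "marked") {
  sel <- !is.na(net$cohort) & net$cohort == cohort
  if (!any(sel))
    stop("cohort '", cohort, "' is extinct (no surviving marked cells)")
  g <- steady$granule[sel, , drop = FALSE]
  frac <- colMeans(g > theta_IEG)
  if (is.null(stimulus)) frac else unname(frac[stimulus])
}
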