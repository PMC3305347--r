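#' Mean-field population parameters (two-connection networks)
#'
#' In the weak-coupling limit (small inhibitory weight, large granule
#' numbers) the network restructuring is described by ODEs for the mean size
#' of each granule-cell population, where a population collects all granule
#' cells sharing the same unordered pair of mitral-cell connections (K = 2).
#' Each population receives a fixed influx `alpha` and loses cells at rate
#' `r(R) = -log T(R)` per cell, with `T` the sigmoidal survival probability
#' of the discrete model evaluated on the population's resilience.
#'
#' @param stimuli A [stimulus_ensemble()] driving the network.
#' @param influx Influx alpha of new granule cells per population per unit
#'   time (> 0).
#' @param inh_weight Inhibitory weight w.
#' @param resilience_threshold,survival_threshold,steepness As in
#'   [survival_params()].
#' @param spontaneous Spontaneous mitral activity s0.
#' @return An object of class `population_params`.
#' @export
population_params <- function(stimuli, influx, inh_weight,
                              resilience_threshold, survival_threshold,
                              steepness, spontaneous = 0.1) {
  stopifnot(inherits(stimuli, "stimulus_ensemble"), influx >= 0,
            inh_weight >= 0, resilience_threshold >= 0,
            survival_threshold >= 0, steepness > 0, spontaneous >= 0)
  M <- n_channels(stimuli)
  pairs <- t(utils::combn(M, 2L))
  structure(list(stimuli = stimuli, M = M, pairs = pairs,
                 influx = influx, inh_weight = inh_weight,
                 resilience_threshold = resilience_threshold,
                 survival_threshold = survival_threshold,
                 steepness = steepness, spontaneous = spontaneous),
            class = "population_params")
}

#' Convenience constructor for the symmetric four-stimulus caricature
#'
#' Builds [population_params()] on the [generate_symmetric4()] ensemble. The
#' analytical treatment trains on the slightly simplified ensemble with
#' `similarity = 1` (identical pair members), for which only two distinct
#' populations remain: the co-active populations (pairs 1-2 and 3-4) and the
#' interfering populations (the four cross pairs).
#'
#' @param amplitudes Strong/weak levels passed to [generate_symmetric4()].
#' @param similarity Training similarity (1 for the analytical setting).
#' @inheritParams population_params
#' @export
symmetric4_population_params <- function(influx, inh_weight,
                                         resilience_threshold,
                                         survival_threshold, steepness,
                                         spontaneous = 0.1,
                                         amplitudes = c(strong = 1, weak = 0.2),
                                         similarity = 1) {
  population_params(generate_symmetric4(similarity, amplitudes), influx,
                    inh_weight, resilience_threshold, survival_threshold,
                    steepness, spontaneous)
}

# effective connectivity of a K = 2 population state: each population of size
# n connecting (i, j) contributes w*n to W[i,i], W[j,j], W[i,j], W[j,i]
population_connectivity <- function(n, params) {
  W <- matrix(0, params$M, params$M)
  w <- params$inh_weight
  for (p in seq_len(nrow(params$pairs))) {
    i <- params$pairs[p, 1L]; j <- params$pairs[p, 2L]
    W[i, i] <- W[i, i] + w * n[p]
    W[j, j] <- W[j, j] + w * n[p]
    W[i, j] <- W[i, j] + w * n[p]
    W[j, i] <- W[j, i] + w * n[p]
  }
  W
}

# steady-state activities and per-population resilience for a population state
population_resilience <- function(n, params) {
  W <- population_connectivity(n, params)
  drive <- params$stimuli$patterns + params$spontaneous
  m <- solve(diag(params$M) + W, drive)
  g <- m[params$pairs[, 1L], , drop = FALSE] +
       m[params$pairs[, 2L], , drop = FALSE]
  R <- rowSums(pmax(g - params$resilience_threshold, 0))
  list(mitral = m, granule = g, resilience = R)
}

# removal rate r(R) = -log T(R); computed on the log scale so that a steep
# sigmoid far below threshold yields k*(theta_S - R) instead of overflowing
population_removal_rate <- function(R, params) {
  -stats::plogis(params$steepness * (R - params$survival_threshold),
                 log.p = TRUE)
}

#' Mean-field time derivatives
#'
#' Right-hand side of the population ODEs,
#' `dn_p/dt = alpha - r(R_p(n)) * n_p`, in the signature expected by
#' [deSolve::ode()]. The resilience of each population is evaluated on the
#' steady-state activities of the linear network implied by the current mean
#' population sizes.
#'
#' @param t Time (unused; the system is autonomous).
#' @param n Population-size state vector, one entry per unordered mitral pair
#'   (order of `params$pairs`).
#' @param params A [population_params()].
#' @return `list(dn)` as required by deSolve.
#' @export
population_rhs <- function(t, n, params) {
  res <- population_resilience(pmax(n, 0), params)
  r <- population_removal_rate(res$resilience, params)
  list(params$influx - r * pmax(n, 0))
}

#' Integrate the mean-field populations forward in time
#'
#' @param params A [population_params()].
#' @param n0 Initial population sizes (default: all zero, the empty network).
#' @param t_end Final time.
#' @param n_out Number of output times.
#' @param ... Passed to [deSolve::ode()] (method defaults to `lsoda`).
#' @return A list: `times`, `trajectory` (times x populations matrix),
#'   `final` (final state vector), `pairs`.
#' @export
integrate_population <- function(params, n0 = NULL, t_end = 2000,
                                 n_out = 400, ...) {
  P <- nrow(params$pairs)
  if (is.null(n0)) n0 <- rep(0, P)
  stopifnot(length(n0) == P, all(n0 >= 0))
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = n0, times = times, func = population_rhs,
                      parms = params, rtol = 1e-10, atol = 1e-10, ...)
  traj <- unname(sol[, -1L, drop = FALSE])
  list(times = sol[, 1L], trajectory = traj,
       final = traj[nrow(traj), ], pairs = params$pairs)
}

# damped Newton with numerical Jacobian on F(n) = alpha - r(R(n)) n
population_newton <- function(params, init, tol = 1e-12, max_iter = 200) {
  Fn <- function(n) {
    res <- population_resilience(n, params)
    params$influx - population_removal_rate(res$resilience, params) * n
  }
  n <- pmax(init, 1e-8)
  for (it in seq_len(max_iter)) {
    f <- Fn(n)
    if (max(abs(f)) < tol * max(1, params$influx)) break
    P <- length(n)
    J <- matrix(0, P, P)
    h <- pmax(abs(n), 1) * 1e-7
    for (k in seq_len(P)) {
      nk <- n; nk[k] <- nk[k] + h[k]
      J[, k] <- (Fn(nk) - f) / h[k]
    }
    delta <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(delta)) stop("singular Jacobian in population fixed point")
    lambda <- 1
    repeat {
      cand <- pmax(n + lambda * delta, 0)
      if (max(abs(Fn(cand))) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    n <- cand
  }
  if (max(abs(Fn(n))) >= 1e-6)
    stop("population fixed point did not converge")
  n
}

#' Fixed point of the general mean-field populations
#'
#' Solves `alpha = r(R_p(n)) n_p` for all populations by a damped Newton
#' iteration with numerical Jacobian.
#'
#' @param params A [population_params()].
#' @param init Initial guess (defaults to a short forward integration).
#' @return The fixed-point state vector (order of `params$pairs`).
#' @export
fixed_point_population <- function(params, init = NULL) {
  if (is.null(init))
    init <- integrate_population(params, t_end = 1500, n_out = 50)$final
  population_newton(params, init)
}

# steep-limit closed forms for the symmetric-4 caricature ---------------------

.sym4_amplitudes <- function(params) {
  S <- unname(params$stimuli$patterns)
  c(a = S[1L, 1L], b = S[3L, 1L])
}

#' Closed-form fixed point of the symmetric-4 caricature
#'
#' For the four-stimulus, four-glomerulus ensemble (training similarity 1)
#' the symmetry leaves two distinguished populations: the co-active
#' population `n_C` (pairs 1-2 and 3-4) and the interfering population `n_I`
#' (the four cross pairs). With `method = "exact"` the finite-steepness
#' fixed-point equations are solved numerically (Newton, exploiting no
#' symmetry); with `method = "closed_form"` the steep-sigmoid-limit formulas
#' are returned:
#' * interior regime (`theta_low < theta_R < theta_crit`): the co-active
#'   population is pinned by the within-stimulus activity difference,
#'   `1 + 2 w n_C = 4 (a - b) / theta_S`, and the interfering population by
#'   the total activity, `1 + 2 w (n_C + 2 n_I) =
#'   (a + b + 2 s0) / (theta_R + theta_S / 4)`;
#' * boundary regime (`theta_R >= theta_crit`): `n_I = 0` and
#'   `1 + 2 w n_C = 2 (a + s0) / (theta_R + theta_S / 2)`;
#' * uniform regime (`theta_R <= theta_low`): the rectifier never clips and
#'   both populations are equal.
#'
#' The regimes meet continuously at `theta_crit` (see [optimal_threshold()]).
#'
#' @param params A [population_params()] built on the similarity-1
#'   symmetric-4 ensemble (see [symmetric4_population_params()]).
#' @param method `"exact"` or `"closed_form"`.
#' @return A list: `coactive`, `interfering`, `regime`
#'   (`"uniform"`, `"interior"` or `"boundary"`), and (exact method) the full
#'   state vector `state`.
#' @export
fixed_point_symmetric4 <- function(params, method = c("exact", "closed_form")) {
  method <- match.arg(method)
  stopifnot(params$M == 4L, params$influx > 0)
  ab <- .sym4_amplitudes(params)
  a <- ab["a"]; b <- ab["b"]
  s0 <- params$spontaneous; w <- params$inh_weight
  thR <- params$resilience_threshold; thS <- params$survival_threshold
  th_crit <- thS * (a + b + 2 * s0) / (4 * (a - b)) - thS / 4
  # the interior (clipped) regime requires the within-stimulus activity
  # difference to be able to reach theta_S / 4; below th_low (or whenever
  # 4 (a - b) <= theta_S) the rectifier never clips and the two populations
  # coincide
  never_clips <- 4 * (a - b) <= thS
  th_low <- if (never_clips) Inf
            else (a + b + 2 * s0) / (12 * (a - b) / thS - 2) - thS / 4
  regime <- if (thR >= th_crit) "boundary"
            else if (never_clips || thR <= th_low) "uniform" else "interior"

  closed <- switch(regime,
    interior = {
      nC <- (4 * (a - b) / thS - 1) / (2 * w)
      nI <- (((a + b + 2 * s0) / (thR + thS / 4) - 1) / (2 * w) - nC) / 2
      c(nC, nI)
    },
    boundary = {
      nC <- (2 * (a + s0) / (thR + thS / 2) - 1) / (2 * w)
      c(nC, 0)
    },
    uniform = {
      n <- ((a + b + 2 * s0) / (thR + thS / 4) - 1) / (6 * w)
      c(n, n)
    })
  if (any(closed < 0))
    stop("no admissible fixed point for these parameters")
  if (method == "closed_form")
    return(list(coactive = unname(closed[1L]), interfering = unname(closed[2L]),
                regime = regime))
  # exact finite-steepness fixed point, initialized from the closed form
  co_idx <- which((params$pairs[, 1L] == 1L & params$pairs[, 2L] == 2L) |
                  (params$pairs[, 1L] == 3L & params$pairs[, 2L] == 4L))
  init <- rep(closed[2L], nrow(params$pairs))
  init[co_idx] <- closed[1L]
  state <- population_newton(params, pmax(init, params$influx))
  list(coactive = mean(state[co_idx]),
       interfering = mean(state[-co_idx]),
       regime = regime, state = state)
}

#' Optimal resilience threshold of the symmetric-4 caricature
#'
#' The smallest resilience threshold for which the interfering population
#' vanishes in the steep-sigmoid limit,
#' `theta_crit = theta_S * (a + b + 2 s0) / (4 (a - b)) - theta_S / 4`.
#' Below it the interfering population is positive (interference raises the
#' within-pair output correlation); above it the co-active population --- and
#' with it the useful inhibition --- starts to decrease. The within-pair
#' output correlation is therefore minimized at this threshold.
#'
#' @param params A [population_params()] on the symmetric-4 ensemble.
#' @return The critical threshold value.
#' @export
optimal_threshold <- function(params) {
  stopifnot(params$M == 4L)
  ab <- .sym4_amplitudes(params)
  thS <- params$survival_threshold
  unname(thS * (ab["a"] + ab["b"] + 2 * params$spontaneous) /
           (4 * (ab["a"] - ab["b"])) - thS / 4)
}

#' Within-pair output correlation of the symmetric-4 network
#'
#' For test stimuli of similarity `q < 1` processed by the symmetric-4
#' network with co-active population `coactive` and interfering population
#' `interfering`, the eigen-decomposition of the effective connectivity gives
#' the exact within-pair Pearson correlation
#' `r = (2 B^2 - D^2) / (2 B^2 + D^2)` with
#' `B = (u - b) / (2 (1 + 2 w n_C))`, `D = d / (1 + 2 w n_I)`,
#' `u = a (1 + q) / 2`, `d = a (1 - q) / 2`. For highly similar stimuli this
#' expands to `r ~ 1 - 4 d^2 (1 + 2 w n_C)^2 / ((u - b)^2 (1 + 2 w n_I)^2)`:
#' the correlation decreases with increasing co-active inhibition and
#' increases with increasing interfering strength.
#'
#' @param params A [population_params()] on the symmetric-4 ensemble.
#' @param coactive,interfering Population sizes.
#' @param similarity Test similarity `q` (near 1).
#' @param expansion If `TRUE` return the leading-order expansion instead of
#'   the exact ratio.
#' @return The within-pair Pearson correlation (approximate or exact).
#' @export
correlation_expansion <- function(params, coactive, interfering,
                                  similarity = 0.9, expansion = FALSE) {
  ab <- .sym4_amplitudes(params)
  a <- ab["a"]; b <- ab["b"]; w <- params$inh_weight
  u <- a * (1 + similarity) / 2
  d <- a * (1 - similarity) / 2
  B <- (u - b) / (2 * (1 + 2 * w * coactive))
  D <- d / (1 + 2 * w * interfering)
  if (expansion) return(unname(1 - (D / B)^2))
  unname((2 * B^2 - D^2) / (2 * B^2 + D^2))
}

#' Steep-limit nullclines of the two symmetric-4 populations
#'
#' Curves in the `(coactive, interfering)` plane on which each population's
#' resilience equals the survival threshold (the steep-sigmoid approximation
#' of the true nullclines `alpha = r(R) n`). Returned as the interfering
#' population size on each curve as a function of the co-active size.
#'
#' @param params A [population_params()] on the symmetric-4 ensemble.
#' @param coactive_grid Grid of co-active population sizes.
#' @return A data frame: `coactive`, `interfering_on_coactive_nullcline`
#'   (R_C = theta_S), `interfering_on_interfering_nullcline`
#'   (R_I = theta_S); `NA` where a curve has no nonnegative solution.
#' @export
nullclines_symmetric4 <- function(params, coactive_grid) {
  stopifnot(params$M == 4L)
  resil <- function(nC, nI, pop) {
    state <- rep(nI, nrow(params$pairs))
    co_idx <- which((params$pairs[, 1L] == 1L & params$pairs[, 2L] == 2L) |
                    (params$pairs[, 1L] == 3L & params$pairs[, 2L] == 4L))
    state[co_idx] <- nC
    R <- population_resilience(state, params)$resilience
    if (pop == "C") R[co_idx[1L]] else R[setdiff(seq_along(R), co_idx)[1L]]
  }
  solve_nI <- function(nC, pop) {
    f <- function(nI) resil(nC, nI, pop) - params$survival_threshold
    lo <- f(0)
    if (lo < 0) return(NA_real_)  # even an empty interfering pool is below threshold
    hi <- 1
    while (f(hi) > 0 && hi < 1e9) hi <- hi * 2
    if (f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  data.frame(
    coactive = coactive_grid,
    interfering_on_coactive_nullcline =
      vapply(coactive_grid, solve_nI, numeric(1), pop = "C"),
    interfering_on_interfering_nullcline =
      vapply(coactive_grid, solve_nI, numeric(1), pop = "I"))
}

#' Alternating- versus mixture-protocol populations
#'
#' Compares the mean-field fixed points reached when training with the four
#' alternating stimuli (similarity-1 symmetric-4 ensemble) versus with four
#' presentations of their 50:50 mixture (all four glomeruli equally driven at
#' `(a + b) / 2`). Because the total resilience of the mixed granule cells is
#' the same in both protocols, the mixture-protocol population satisfies
#' `3 n_mix = n_C + 2 n_I` in the steep limit and hence falls strictly
#' between the alternating protocol's interfering ("mixed") and co-active
#' ("pure") populations whenever those differ.
#'
#' @param params A [population_params()] on the symmetric-4 ensemble
#'   (alternating protocol); the mixture ensemble is derived from it.
#' @param method `"exact"` or `"closed_form"`, as in
#'   [fixed_point_symmetric4()].
#' @return A list: `p_mixture`, `p_pure_alt` (co-active), `p_mixed_alt`
#'   (interfering), and `ordering_holds`
#'   (`p_mixed_alt < p_mixture < p_pure_alt`).
#' @export
mixture_comparison <- function(params, method = c("exact", "closed_form")) {
  method <- match.arg(method)
  alt <- fixed_point_symmetric4(params, method = method)
  ab <- .sym4_amplitudes(params)
  mixed_level <- (ab["a"] + ab["b"]) / 2
  mix_stim <- stimulus_ensemble(
    matrix(mixed_level, nrow = 4L, ncol = 4L),
    labels = paste0("mixture_", 1:4))
  mix_params <- params
  mix_params$stimuli <- mix_stim
  p_mix <- if (method == "closed_form") {
    thR <- params$resilience_threshold; thS <- params$survival_threshold
    ((2 * mixed_level + 2 * params$spontaneous) / (thR + thS / 4) - 1) /
      (6 * params$inh_weight)
  } else {
    mean(fixed_point_population(mix_params))
  }
  p_mix <- unname(p_mix)
  list(p_mixture = p_mix, p_pure_alt = alt$coactive,
       p_mixed_alt = alt$interfering,
       ordering_holds = alt$interfering < p_mix && p_mix < alt$coactive)
}
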