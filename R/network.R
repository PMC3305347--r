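#' Mitral-granule network state
#'
#' Creates a recurrent bulbar network of `n_mitral` principal (mitral) cells
#' and an initial cohort of inhibitory granule cells. Each granule cell is
#' excited by `connections` distinct, uniformly chosen mitral cells (excitatory
#' weight fixed at 1) and, through the reciprocal dendrodendritic synapses,
#' inhibits the same mitral cells with weight `inh_weight`. Connections are
#' stored as index matrices (`exc`, `inh`: granule x K) plus per-synapse
#' inhibitory weights (`inh_w`).
#'
#' @param n_mitral Number of mitral cells (input channels).
#' @param connections Connections per granule cell, K (`1 <= K <= n_mitral`).
#' @param inh_weight Inhibitory synaptic weight w (>= 0).
#' @param spontaneous Spontaneous mitral activity s0 (activity in the absence
#'   of stimulus and inhibition).
#' @param n_granule Initial number of granule cells (wired at random).
#' @return An object of class `bulb_network`.
#' @examples
#' set.seed(1)
#' net <- new_network(n_mitral = 10, connections = 4, inh_weight = 0.05,
#'                    spontaneous = 0.1, n_granule = 20)
#' net
#' @export
new_network <- function(n_mitral, connections = 8, inh_weight = 0.01,
                        spontaneous = 0.1, n_granule = 0) {
  stopifnot(n_mitral >= 1, connections >= 1, connections <= n_mitral,
            inh_weight >= 0, spontaneous >= 0, n_granule >= 0)
  net <- structure(
    list(M = as.integer(n_mitral), K = as.integer(connections),
         w = inh_weight, spontaneous = spontaneous,
         exc = matrix(integer(0), 0L, connections),
         inh = matrix(integer(0), 0L, connections),
         inh_w = matrix(numeric(0), 0L, connections),
         birth_step = integer(0), cohort = character(0)),
    class = "bulb_network")
  if (n_granule > 0) net <- add_granule_cells(net, n_granule, step = 0L)
  net
}

#' @export
print.bulb_network <- function(x, ...) {
  cat(sprintf("<bulb_network> %d mitral, %d granule cells (K = %d, w = %g, s0 = %g)\n",
              x$M, n_granule_cells(x), x$K, x$w, x$spontaneous))
  invisible(x)
}

#' Number of granule cells in a network
#' @param net A `bulb_network`.
#' @export
n_granule_cells <- function(net) nrow(net$exc)

#' Add newborn granule cells
#'
#' Wires `n` new granule cells into the network, each to `net$K` distinct,
#' uniformly chosen mitral cells, with reciprocal synapses of weight `net$w`.
#' Uses the current RNG state.
#'
#' @param net A `bulb_network`.
#' @param n Number of cells to add.
#' @param step Birth step recorded for cohort tracking.
#' @param cohort Cohort tag for the new cells.
#' @export
add_granule_cells <- function(net, n, step = NA_integer_, cohort = NA_character_) {
  if (n == 0) return(net)
  new_exc <- t(vapply(seq_len(n), function(i) sample.int(net$M, net$K),
                      integer(net$K)))
  new_exc <- matrix(new_exc, nrow = n)  # guard K = 1 drop
  net$exc <- rbind(net$exc, new_exc)
  net$inh <- rbind(net$inh, new_exc)    # full reciprocity at birth
  net$inh_w <- rbind(net$inh_w, matrix(net$w, n, net$K))
  net$birth_step <- c(net$birth_step, rep(as.integer(step), n))
  net$cohort <- c(net$cohort, rep(cohort, n))
  net
}

remove_granule_cells <- function(net, keep) {
  net$exc <- net$exc[keep, , drop = FALSE]
  net$inh <- net$inh[keep, , drop = FALSE]
  net$inh_w <- net$inh_w[keep, , drop = FALSE]
  net$birth_step <- net$birth_step[keep]
  net$cohort <- net$cohort[keep]
  net
}

# granule x mitral sparse incidence matrices
exc_incidence <- function(net) {
  G <- n_granule_cells(net)
  Matrix::sparseMatrix(i = rep(seq_len(G), net$K), j = as.vector(net$exc),
                       x = 1, dims = c(G, net$M))
}

inh_incidence <- function(net) {
  G <- n_granule_cells(net)
  Matrix::sparseMatrix(i = rep(seq_len(G), net$K), j = as.vector(net$inh),
                       x = as.vector(net$inh_w), dims = c(G, net$M))
}

#' Effective mitral-mitral connectivity
#'
#' The disynaptic inhibition between mitral cells mediated by the granule
#' cells: entry (i, k) sums, over granule cells, the inhibitory weight onto
#' mitral cell i times the excitatory indicator from mitral cell k. Under full
#' reciprocity and uniform weights this is w times the number of granule cells
#' shared by i and k (a Gram matrix, hence symmetric positive semi-definite);
#' diagonal entries are self-inhibition.
#'
#' @param net A `bulb_network`.
#' @return A dense `M x M` matrix.
#' @export
effective_connectivity <- function(net) {
  if (n_granule_cells(net) == 0L) return(matrix(0, net$M, net$M))
  as.matrix(Matrix::t(inh_incidence(net)) %*% exc_incidence(net))
}

#' Solve network steady state
#'
#' Computes the steady-state mitral and granule activities for every stimulus
#' in the ensemble. With linear coupling the granule activities are the summed
#' activities of their source mitral cells, so the mitral steady state reduces
#' to one linear solve per stimulus, `(I + W) m = S + s0`, with `W` the
#' effective connectivity; with rectified (threshold-linear) coupling a damped
#' fixed-point iteration is used. For sufficiently large spontaneous activity
#' the two coincide because all activities stay positive.
#'
#' @param net A `bulb_network`.
#' @param ensemble A [stimulus_ensemble()] with `net$M` channels.
#' @param coupling `"linear"` (default) or `"rectified"`.
#' @param W Optional effective-connectivity override (e.g. after
#'   [rescale_self_inhibition()]); linear coupling only.
#' @param tol,max_iter Convergence control for the rectified iteration.
#' @param damping Fixed-point damping factor in (0, 1].
#' @return An object of class `steady_state` with `mitral` (M x stimuli),
#'   `granule` (G x stimuli) and `residual` (max fixed-point violation).
#' @export
solve_steady_state <- function(net, ensemble, coupling = c("linear", "rectified"),
                               W = NULL, tol = 1e-10, max_iter = 1e5,
                               damping = 0.5) {
  coupling <- match.arg(coupling)
  stopifnot(inherits(ensemble, "stimulus_ensemble"))
  S <- ensemble$patterns
  if (nrow(S) != net$M)
    stop("ensemble channel count does not match the number of mitral cells")
  drive <- S + net$spontaneous
  G <- n_granule_cells(net)
  E <- if (G > 0) exc_incidence(net) else NULL

  if (coupling == "linear") {
    if (is.null(W)) W <- effective_connectivity(net)
    A <- diag(net$M) + W
    m <- tryCatch(solve(A, drive), error = function(e)
      stop("singular or ill-conditioned steady-state system: ", conditionMessage(e)))
    g <- if (G > 0) as.matrix(E %*% m) else matrix(0, 0L, ncol(S))
    residual <- max(abs(A %*% m - drive))
  } else {
    if (!is.null(W))
      stop("connectivity override is only supported with linear coupling")
    # Because the excitatory weights are nonnegative, the granule rectifier
    # cannot bind once the mitral activities are clipped at zero; the
    # rectified steady state therefore reduces to the complementarity
    # problem m = max(drive - W m, 0), solved per stimulus by active-set
    # (policy) iteration with a damped fixed-point fallback.
    Weff <- effective_connectivity(net)
    m <- matrix(0, net$M, ncol(S))
    for (s in seq_len(ncol(S))) {
      d <- drive[, s]
      active <- d > 0
      prev_active <- NULL
      ms <- numeric(net$M)
      converged <- FALSE
      for (iter in seq_len(40L)) {
        ms[] <- 0
        if (any(active)) {
          A <- which(active)
          ms[A] <- tryCatch(
            solve(diag(length(A)) + Weff[A, A, drop = FALSE], d[A]),
            error = function(e) rep(NA_real_, length(A)))
          if (anyNA(ms)) break
        }
        q <- d - drop(Weff %*% pmax(ms, 0))
        new_active <- q > 0
        if (identical(new_active, active) && all(ms[active] >= -tol)) {
          converged <- TRUE
          break
        }
        if (identical(new_active, prev_active)) break  # period-2 cycle
        prev_active <- active
        active <- new_active
      }
      ms <- pmax(ms, 0)
      if (!converged ||
          max(abs(ms - pmax(d - drop(Weff %*% ms), 0))) >= sqrt(tol)) {
        # fallback: damped iteration with a step size bounded through the
        # largest row sum of the inhibition (Gershgorin bound)
        mu_max <- max(1, rowSums(abs(Weff)))
        eta <- min(damping, 1.5 / (1 + mu_max))
        ms <- pmax(d, 0)
        for (iter in seq_len(max_iter)) {
          target <- pmax(d - drop(Weff %*% ms), 0)
          if (max(abs(target - ms)) < tol) { ms <- target; break }
          ms <- (1 - eta) * ms + eta * target
        }
      }
      resid_s <- max(abs(ms - pmax(d - drop(Weff %*% ms), 0)))
      if (resid_s >= sqrt(tol))
        stop(sprintf(paste("rectified steady state did not converge",
                           "(residual %.3g); likely an unstable",
                           "strong-inhibition regime"), resid_s))
      m[, s] <- ms
    }
    g <- if (G > 0) pmax(as.matrix(E %*% m), 0) else matrix(0, 0L, ncol(S))
    residual <- max(abs(m - pmax(drive - Weff %*% m, 0)))
  }
  dimnames(m) <- list(NULL, ensemble$labels)
  structure(list(mitral = m, granule = g, residual = residual,
                 labels = ensemble$labels),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> %d mitral x %d stimuli (%d granule cells), residual %.2g\n",
              nrow(x$mitral), ncol(x$mitral), nrow(x$granule), x$residual))
  invisible(x)
}

#' Redirect a fraction of inhibitory connections
#'
#' Perturbs the reciprocity of the dendrodendritic synapses: for each granule
#' cell, `round(fraction * K)` of its inhibitory targets are replaced by
#' uniformly chosen mitral cells (resampling collisions so that no granule
#' cell inhibits the same mitral cell twice). Excitatory sources and synaptic
#' weights are unchanged. Uses the current RNG state.
#'
#' @param net A `bulb_network`.
#' @param fraction Fraction of inhibitory connections to rewire, in `[0, 1]`.
#' @export
rewire <- function(net, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  n_rw <- round(fraction * net$K)
  if (n_rw == 0L || n_granule_cells(net) == 0L) return(net)
  for (j in seq_len(n_granule_cells(net))) {
    slots <- if (n_rw == net$K) seq_len(net$K) else sample.int(net$K, n_rw)
    targets <- net$inh[j, ]
    # draw the replacements jointly and uniformly from the mitral cells not
    # already kept, so fully rewired targets are a uniform K-subset
    # (statistically independent of the excitatory sources)
    pool <- setdiff(seq_len(net$M), targets[-slots])
    targets[slots] <- sample(pool, n_rw)
    net$inh[j, ] <- targets
  }
  net
}

#' Randomize inhibitory synaptic weights
#'
#' Emulates the variable efficacy of inhibitory synapses located at different
#' dendritic distances from the mitral soma. `two_point` draws each weight
#' with equal probability from `w - delta` and `w + delta`; `uniform` draws it
#' uniformly on `[w - delta, w + delta]`. Either way the expected weight stays
#' at `w`. Uses the current RNG state.
#'
#' @param net A `bulb_network`.
#' @param mode `"two_point"` or `"uniform"`.
#' @param delta Heterogeneity half-width, `0 <= delta <= w` (at `delta = w`
#'   under `two_point` about half of the synapses become ineffective).
#' @export
heterogenize_weights <- function(net, mode = c("two_point", "uniform"), delta) {
  mode <- match.arg(mode)
  if (delta < 0 || delta > net$w)
    stop("require 0 <= delta <= w (weights must stay nonnegative)")
  n <- length(net$inh_w)
  if (n == 0L || delta == 0) return(net)
  draw <- if (mode == "two_point") {
    net$w + delta * sample(c(-1, 1), n, replace = TRUE)
  } else {
    stats::runif(n, net$w - delta, net$w + delta)
  }
  net$inh_w <- matrix(draw, nrow = nrow(net$inh_w))
  net
}

#' Rebalance self- versus lateral inhibition
#'
#' Rescales the diagonal (self-inhibition) of an effective connectivity matrix
#' by `gamma` and rescales each row's off-diagonal entries by the row-specific
#' factor that keeps the row sum fixed, so the total inhibition each mitral
#' cell receives is unchanged while its division between self- and lateral
#' inhibition shifts (`gamma < 1`: less self-, more lateral inhibition).
#'
#' @param W Square effective-connectivity matrix.
#' @param gamma Diagonal scale factor (>= 0).
#' @return The rescaled matrix; row sums are preserved to machine precision.
#' @export
rescale_self_inhibition <- function(W, gamma) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), gamma >= 0)
  d <- diag(W)
  rs <- rowSums(W)
  off <- rs - d
  scale <- ifelse(off > 0, (rs - gamma * d) / off, 1)
  if (any(off <= 0 & abs((gamma - 1) * d) > 0))
    stop("row without off-diagonal weight cannot absorb a rescaled diagonal")
  if (any(scale < 0))
    stop("gamma demands negative off-diagonal weights for at least one row")
  Wn <- sweep(W, 1L, scale, `*`)
  diag(Wn) <- gamma * d
  Wn
}

#' Asymmetry of a connectivity matrix
#'
#' Frobenius norm of the anti-symmetric component relative to that of the
#' symmetric component, `||(W - t(W))/2||_F / ||(W + t(W))/2||_F`.
#'
#' @param W Square matrix.
#' @return A scalar ratio (0 for symmetric `W`).
#' @export
asymmetry_ratio <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  s <- (W + t(W)) / 2
  a <- (W - t(W)) / 2
  ns <- norm(s, "F")
  if (ns == 0) stop("symmetric component is zero; ratio undefined")
  norm(a, "F") / ns
}

#' Eigenvalues of the linearized activity dynamics
#'
#' Assumes standard leaky rate dynamics with unit relaxation rate around the
#' steady state of the linear coupling: `dm/dt = -m + drive - t(Winh) g`,
#' `dg/dt = -g + E m`. The spectrum of the Jacobian reduces algebraically to
#' `-1 +/- sqrt(-mu)` over the eigenvalues `mu` of the effective connectivity,
#' plus `-1` with multiplicity `G - M`. Only the signs of the real parts are
#' meaningful (they are invariant to the choice of time constant).
#'
#' @param net A `bulb_network`.
#' @param W Optional effective-connectivity override.
#' @return A list with complex `values` and `max_real`.
#' @export
stability_spectrum <- function(net, W = NULL) {
  if (is.null(W)) W <- effective_connectivity(net)
  mu <- eigen(W, only.values = TRUE)$values
  rt <- sqrt(as.complex(-mu))
  values <- c(-1 + rt, -1 - rt)
  G <- n_granule_cells(net)
  if (G > net$M) values <- c(values, rep(-1 + 0i, G - net$M))
  list(values = values, max_real = max(Re(values)))
}
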