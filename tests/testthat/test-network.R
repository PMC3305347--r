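test_that("new networks wire K distinct random mitral cells per granule cell", {
  set.seed(5)
  net <- new_network(10, connections = 4, inh_weight = 0.05,
                     spontaneous = 0.1, n_granule = 200)
  expect_equal(n_granule_cells(net), 200L)
  expect_equal(ncol(net$exc), 4L)
  # no granule cell connects to any mitral cell twice; full reciprocity
  expect_true(all(apply(net$exc, 1, function(x) !anyDuplicated(x))))
  expect_identical(net$inh, net$exc)
  expect_true(all(net$inh_w == 0.05))
  expect_error(new_network(4, connections = 5), "connections <= n_mitral")
})

test_that("steady state without granule cells is drive plus spontaneous", {
  ens <- generate_symmetric4(0.9)
  net <- new_network(4, connections = 2, spontaneous = 0.25)
  st <- solve_steady_state(net, ens)
  expect_equal(unname(st$mitral), unname(ens$patterns) + 0.25)
  expect_lt(st$residual, 1e-12)
  # zero stimulus: all activities at the spontaneous level
  zero <- stimulus_ensemble(matrix(0, 4, 1))
  expect_equal(unname(solve_steady_state(net, zero)$mitral),
               matrix(0.25, 4, 1))
})

test_that("linear solve agrees with damped fixed-point iteration", {
  # toy 3-cell configuration with a large co-active granule population
  set.seed(8)
  ens <- generate_toy3()
  net <- new_network(3, connections = 2, inh_weight = 0.02, spontaneous = 0.1)
  exc <- rbind(matrix(rep(c(1L, 2L), 40), ncol = 2, byrow = TRUE),
               matrix(rep(c(1L, 3L), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c(2L, 3L), 5), ncol = 2, byrow = TRUE))
  net$exc <- exc; net$inh <- exc
  net$inh_w <- matrix(0.02, nrow(exc), 2)
  net$birth_step <- rep(0L, nrow(exc)); net$cohort <- rep(NA_character_, nrow(exc))

  st <- solve_steady_state(net, ens)
  # independent oracle: damp-iterate the coupled rate equations to convergence
  drive <- ens$patterns + 0.1
  W <- effective_connectivity(net)
  m <- drive
  for (i in 1:20000) m <- 0.9 * m + 0.1 * (drive - W %*% m)
  expect_equal(unname(st$mitral), unname(m), tolerance = 1e-8)
  # granule activity equals the summed source activities
  expect_equal(st$granule[1, ], st$mitral[1, ] + st$mitral[2, ],
               ignore_attr = TRUE)
  # co-active mitral cells are suppressed more than the third
  expect_lt(st$mitral[1, 1] / drive[1, 1], st$mitral[3, 1] / drive[3, 1])
  # selective suppression of the co-active channels decorrelates the pair
  # (a slightly asymmetric variant avoids the rank-2 degeneracy of exactly
  # symmetric three-channel patterns, whose Pearson correlation is +-1)
  ens2 <- stimulus_ensemble(cbind(c(1, 0.95, 0.2), c(0.95, 1, 0)))
  st2 <- solve_steady_state(net, ens2)
  expect_lt(pearson(st2$mitral[, 1], st2$mitral[, 2]),
            pearson(ens2$patterns[, 1], ens2$patterns[, 2]))
})

test_that("rectified coupling matches linear when activities stay positive", {
  set.seed(13)
  ens <- generate_symmetric4(0.9)
  net <- new_network(4, connections = 2, inh_weight = 0.002,
                     spontaneous = 0.2, n_granule = 150)
  lin <- solve_steady_state(net, ens, "linear")
  rec <- solve_steady_state(net, ens, "rectified")
  expect_true(all(lin$mitral > 0))
  expect_equal(rec$mitral, lin$mitral, tolerance = 1e-6)
  # strong uniform inhibition clips weakly driven channels at zero
  strong <- sym4_network(400, 400, w = 0.01)
  recs <- solve_steady_state(strong, ens, "rectified")
  expect_true(all(recs$mitral >= 0))
  expect_true(any(recs$mitral == 0))
  # clipped solution satisfies the complementarity fixed point
  W <- effective_connectivity(strong)
  resid <- recs$mitral - pmax(ens$patterns + 0.1 - W %*% recs$mitral, 0)
  expect_lt(max(abs(resid)), 1e-4)
})

test_that("effective connectivity counts shared granule cells", {
  net <- new_network(5, connections = 2, inh_weight = 0.3)
  expect_equal(effective_connectivity(net), matrix(0, 5, 5))
  net$exc <- net$inh <- matrix(c(1L, 2L), 1)
  net$inh_w <- matrix(0.3, 1, 2)
  net$birth_step <- 0L; net$cohort <- NA_character_
  W <- effective_connectivity(net)
  want <- matrix(0, 5, 5); want[1:2, 1:2] <- 0.3
  expect_equal(W, want)
  # reciprocal uniform-weight networks give symmetric PSD (Gram) matrices
  set.seed(21)
  big <- new_network(12, connections = 4, inh_weight = 0.1, n_granule = 80)
  Wb <- effective_connectivity(big)
  expect_equal(Wb, t(Wb))
  expect_gte(min(eigen(Wb, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
})

test_that("rewiring replaces the requested number of inhibitory targets", {
  set.seed(31)
  net <- new_network(20, connections = 8, inh_weight = 0.1, n_granule = 150)
  expect_identical(rewire(net, 0), net)
  expect_equal(effective_connectivity(rewire(net, 0)),
               effective_connectivity(net))
  half <- rewire(net, 0.5)
  expect_identical(half$exc, net$exc)     # excitatory sources untouched
  # exactly round(0.5 * 8) = 4 slots replaced per cell (collisions resampled)
  changed <- rowSums(half$inh != net$inh)
  expect_true(all(changed <= 4))
  expect_gt(mean(changed), 3)  # a replacement can hit the old target by chance
  expect_true(all(apply(half$inh, 1, function(x) !anyDuplicated(x))))
  # full rewiring: inhibitory targets statistically independent of sources,
  # expected overlap K^2 / M per cell
  full <- rewire(net, 1)
  overlap <- mapply(function(i) length(intersect(full$inh[i, ], full$exc[i, ])),
                    seq_len(150))
  expect_equal(mean(overlap), 8^2 / 20, tolerance = 0.15)
})

test_that("weight heterogeneity keeps the mean weight at w", {
  set.seed(17)
  net <- new_network(10, connections = 4, inh_weight = 0.2, n_granule = 400)
  expect_identical(heterogenize_weights(net, "two_point", 0), net)
  two <- heterogenize_weights(net, "two_point", 0.2)
  # at delta = w about half of the synapses become ineffective
  expect_equal(mean(two$inh_w == 0), 0.5, tolerance = 0.05)
  # sample mean within 3 standard errors of w
  expect_lt(abs(mean(two$inh_w) - 0.2), 3 * 0.2 / sqrt(1600))
  uni <- heterogenize_weights(net, "uniform", 0.1)
  expect_true(all(uni$inh_w >= 0.1 & uni$inh_w <= 0.3))
  expect_lt(abs(mean(uni$inh_w) - 0.2), 3 * (0.1 / sqrt(3)) / sqrt(1600))
  expect_error(heterogenize_weights(net, "two_point", 0.3), "delta <= w")
})

test_that("self-inhibition rescaling preserves row sums exactly", {
  W <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(rescale_self_inhibition(W, 1), W)
  expect_equal(rescale_self_inhibition(W, 0), matrix(c(0, 3, 3, 0), 2))
  set.seed(23)
  for (gamma in c(0, 0.5, 1.3)) {
    Wr <- matrix(runif(36), 6, 6)
    Ws <- rescale_self_inhibition(Wr, gamma)
    expect_equal(rowSums(Ws), rowSums(Wr), tolerance = 1e-15)
    expect_equal(diag(Ws), gamma * diag(Wr))
  }
  # a row whose diagonal dominates cannot absorb a large gamma
  bad <- matrix(c(5, 0.1, 0.1, 5), 2)
  expect_error(rescale_self_inhibition(bad, 2), "negative off-diagonal")
})

test_that("asymmetry ratio is a homogeneous Frobenius ratio", {
  S <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(asymmetry_ratio(S), 0)
  A <- matrix(c(0, -1, 1, 0), 2)
  W <- S + 0.2 * norm(S, "F") / norm(A, "F") * A
  expect_equal(asymmetry_ratio(W), 0.2, tolerance = 1e-12)
  expect_equal(asymmetry_ratio(5 * W), asymmetry_ratio(W))
  expect_error(asymmetry_ratio(matrix(c(0, 1, -1, 0), 2)), "undefined")
})

test_that("stability spectrum reduces correctly and stays negative in the
           operating regime", {
  # uncoupled network: all eigenvalues at the intrinsic relaxation rate
  empty <- new_network(4, connections = 2)
  expect_equal(stability_spectrum(empty)$values, rep(-1 + 0i, 8))

  # algebraic reduction agrees with the full Jacobian spectrum
  set.seed(19)
  net <- new_network(6, connections = 3, inh_weight = 0.15, n_granule = 10)
  net <- rewire(net, 0.5)      # make the connectivity asymmetric
  G <- n_granule_cells(net)
  E <- matrix(0, G, 6); A <- matrix(0, 6, G)
  for (j in seq_len(G)) {
    E[j, net$exc[j, ]] <- 1
    A[net$inh[j, ], j] <- net$inh_w[j, ]
  }
  J <- rbind(cbind(-diag(6), -A), cbind(E, -diag(G)))
  full <- sort(Re(eigen(J, only.values = TRUE)$values))
  reduced <- sort(Re(stability_spectrum(net)$values))
  # the square root in the reduction amplifies rounding near mu = 0, so the
  # comparison is at a few-1e-6 absolute accuracy
  expect_equal(reduced, full, tolerance = 1e-5)

  # eigenvalues move continuously with the coupling strength
  w_small <- net; w_small$inh_w <- net$inh_w * 1e-3
  expect_equal(max(Re(stability_spectrum(w_small)$values)), -1,
               tolerance = 0.05)

  # an evolved reciprocal network in the default regime is stable
  set.seed(2)
  ens <- generate_symmetric4(1)
  params <- survival_params(0.05, 0.4, 50, 12, connections = 2,
                            inh_weight = 0.01, spontaneous = 0.1)
  evo <- new_network(4, connections = 2, inh_weight = 0.01, spontaneous = 0.1)
  for (s in 1:120) evo <- evolution_step(evo, ens, params, step = s)$network
  expect_lt(stability_spectrum(evo)$max_real, 0)
})
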