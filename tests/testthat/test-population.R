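test_that("population derivatives have the stated limits", {
  pp <- sym4_params()
  P <- nrow(pp$pairs)
  # no influx, empty populations: nothing changes
  pp0 <- pp; pp0$influx <- 0
  expect_equal(population_rhs(0, rep(0, P), pp0)[[1]], rep(0, P))
  # certain survival (huge resilience margin): pure growth at the influx
  sure <- sym4_params(resilience_threshold = 0, survival_threshold = 1e-9,
                      steepness = 1e4)
  expect_equal(population_rhs(0, rep(1, P), sure)[[1]], rep(sure$influx, P),
               tolerance = 1e-9)
})

test_that("mean-field derivative matches the discrete chain on one population", {
  # M = 2, K = 2: every granule cell joins the single population {1,2}
  stim <- stimulus_ensemble(matrix(c(1, 0.8), 2, 1))
  pp <- population_params(stim, influx = 6, inh_weight = 0.01,
                          resilience_threshold = 0.05,
                          survival_threshold = 0.4, steepness = 30,
                          spontaneous = 0.1)
  n0 <- 120
  drhs <- population_rhs(0, n0, pp)[[1]]
  # hand-algebra oracle for the derivative: 2x2 steady state, resilience,
  # removal rate -log T, assembled independently of the package internals
  W <- 0.01 * n0 * matrix(1, 2, 2)
  m <- solve(diag(2) + W, c(1, 0.8) + 0.1)
  R <- max(sum(m) - 0.05, 0)
  r <- -log(plogis(30 * (R - 0.4)))
  expect_equal(drhs, 6 - r * n0, tolerance = 1e-12)
  # Monte-Carlo oracle: mean one-step increment of the stochastic chain.
  # The chain assesses the newborn cells in the same step and removes with
  # probability 1 - T instead of rate -log T, so the agreement is to the
  # order of the influx-induced shift of the survival probability.
  params <- survival_params(0.05, 0.4, 30, 6, connections = 2,
                            inh_weight = 0.01, spontaneous = 0.1)
  set.seed(123)
  incr <- replicate(400, {
    net <- new_network(2, connections = 2, inh_weight = 0.01,
                       spontaneous = 0.1, n_granule = n0)
    n_granule_cells(evolution_step(net, stim, params)$network) - n0
  })
  expect_lt(abs(mean(incr) - drhs), 0.35 * pp$influx)
})

test_that("steep-limit nullclines approximate the exact ones and are monotone", {
  pp <- sym4_params(steepness = 3000)
  cf <- fixed_point_symmetric4(pp, "closed_form")
  grid <- seq(0.6, 1.1, length.out = 6) * cf$coactive
  nc <- nullclines_symmetric4(pp, grid)
  # on the interfering nullcline the interfering population falls as the
  # co-active population grows (inhibition lowers activity)
  iline <- nc$interfering_on_interfering_nullcline
  ok <- !is.na(iline)
  expect_true(all(diff(iline[ok]) < 0))
  # steep-limit line: n_C + 2 n_I at constant total; compare with the
  # closed-form relation
  a <- 1; b <- 0.2
  total <- ((a + b + 2 * pp$spontaneous) /
              (pp$resilience_threshold + pp$survival_threshold / 4) - 1) /
           (2 * pp$inh_weight)
  expect_equal(grid[ok] + 2 * iline[ok], rep(total, sum(ok)),
               tolerance = 1e-2)
  # stimulus symmetry: nullclines built from the mirrored stimuli coincide
  ppm <- pp
  ppm$stimuli <- stimulus_ensemble(pp$stimuli$patterns[c(3, 4, 1, 2),
                                                       c(3, 4, 1, 2)])
  ncm <- nullclines_symmetric4(ppm, grid)
  expect_equal(ncm, nc, tolerance = 1e-9)
})

test_that("closed-form fixed points are continuous and regime-correct", {
  th_crit <- optimal_threshold(sym4_params())
  expect_equal(th_crit, 0.4 * 1.4 / 3.2 - 0.1, tolerance = 1e-12)
  # interior below, boundary above, continuity at the critical threshold
  lo <- fixed_point_symmetric4(sym4_params(th_crit - 0.01), "closed_form")
  hi <- fixed_point_symmetric4(sym4_params(th_crit + 0.01), "closed_form")
  at <- fixed_point_symmetric4(sym4_params(th_crit), "closed_form")
  expect_equal(lo$regime, "interior")
  expect_equal(hi$regime, "boundary")
  expect_gt(lo$interfering, 0)
  expect_equal(hi$interfering, 0)
  just_below <- fixed_point_symmetric4(sym4_params(th_crit - 1e-9),
                                       "closed_form")
  expect_equal(at$coactive, just_below$coactive, tolerance = 1e-6)
  expect_lt(just_below$interfering, 1e-4)
  # below the critical threshold the co-active population is pinned;
  # above it, it decreases with the threshold
  lo2 <- fixed_point_symmetric4(sym4_params(th_crit - 0.03), "closed_form")
  expect_equal(lo2$coactive, lo$coactive)
  hi2 <- fixed_point_symmetric4(sym4_params(th_crit + 0.03), "closed_form")
  expect_lt(hi2$coactive, hi$coactive)
  # all populations nonnegative in every regime
  for (th in seq(0.01, 0.2, by = 0.02)) {
    fp <- fixed_point_symmetric4(sym4_params(th), "closed_form")
    expect_gte(fp$coactive, 0); expect_gte(fp$interfering, 0)
  }
})

test_that("the critical threshold is where interference vanishes (scan oracle)", {
  # bisection-free oracle: scan the exact fixed point on a fine grid and
  # locate the smallest threshold with (essentially) no interfering cells
  th_crit <- optimal_threshold(sym4_params())
  grid <- seq(0.04, 0.11, by = 0.005)
  interf <- vapply(grid, function(th)
    fixed_point_symmetric4(sym4_params(th, steepness = 3000),
                           "exact")$interfering, numeric(1))
  floor_level <- 0.05 * max(interf)
  first_zero <- grid[min(which(interf < floor_level))]
  expect_lt(abs(first_zero - th_crit), 0.0051)
})

test_that("phase-plane trajectory grows linearly, then slides to the fixed point", {
  pp <- sym4_params(steepness = 400)
  sol <- integrate_population(pp, t_end = 3000, n_out = 300)
  co_idx <- which((pp$pairs[, 1] == 1 & pp$pairs[, 2] == 2) |
                  (pp$pairs[, 1] == 3 & pp$pairs[, 2] == 4))
  # early growth is linear at the influx rate for every population
  t10 <- which.min(abs(sol$times - 10))
  expect_equal(sol$trajectory[t10, ], rep(pp$influx * sol$times[t10], 6),
               tolerance = 0.02)
  # the final state matches the Newton fixed point
  fp <- fixed_point_symmetric4(pp, "exact")
  expect_equal(mean(sol$final[co_idx]), fp$coactive, tolerance = 1e-6)
  expect_equal(mean(sol$final[-co_idx]), fp$interfering, tolerance = 1e-5)
  # the interfering populations are captured by their nullcline first and
  # stall while the co-active populations keep growing
  mid <- which.min(abs(sol$times - 300))
  expect_gt(sol$trajectory[nrow(sol$trajectory), co_idx[1]],
            1.5 * sol$trajectory[mid, co_idx[1]] - sol$trajectory[mid, co_idx[1]])
  expect_lt(max(sol$trajectory[mid:300, -co_idx[1]][, 3]),
            1.2 * sol$final[3])
})

test_that("correlation expansion agrees with the exactly solved 4-cell network", {
  pp <- sym4_params()
  for (q in c(0.85, 0.95)) {
    for (pops in list(c(300, 40), c(150, 0), c(80, 80))) {
      # dual route: eigenmode formula vs full linear network solve
      approx_r <- correlation_expansion(pp, pops[1], pops[2], similarity = q)
      net <- sym4_network(pops[1], pops[2], w = pp$inh_weight)
      test_ens <- generate_symmetric4(q)
      st <- solve_steady_state(net, test_ens)
      exact_r <- pearson(st$mitral[, 1], st$mitral[, 2])
      expect_equal(approx_r, exact_r, tolerance = 1e-10)
      # leading-order expansion approaches the exact value near q = 1
      expect_equal(correlation_expansion(pp, pops[1], pops[2],
                                         similarity = q, expansion = TRUE),
                   exact_r, tolerance = (1 - q)^2 * 30 + 1e-6)
    }
  }
  # no network: the uninhibited input correlation
  in_r <- pearson(generate_symmetric4(0.9)$patterns[, 1],
                  generate_symmetric4(0.9)$patterns[, 2])
  expect_equal(correlation_expansion(pp, 0, 0, similarity = 0.9), in_r,
               tolerance = 1e-12)
  # monotonicity: decreasing in co-active, increasing in interfering strength
  expect_lt(correlation_expansion(pp, 400, 40),
            correlation_expansion(pp, 300, 40))
  expect_gt(correlation_expansion(pp, 300, 80),
            correlation_expansion(pp, 300, 40))
})

test_that("the mixture protocol population lies between the alternating ones", {
  pp <- sym4_params(steepness = 400)
  mc <- mixture_comparison(pp, "exact")
  expect_true(mc$ordering_holds)
  expect_lt(mc$p_mixed_alt, mc$p_mixture)
  expect_lt(mc$p_mixture, mc$p_pure_alt)
  # closed form: equal-total-resilience matching gives the exact average
  cc <- mixture_comparison(sym4_params(steepness = 3000), "closed_form")
  expect_equal(3 * cc$p_mixture, cc$p_pure_alt + 2 * cc$p_mixed_alt,
               tolerance = 1e-9)
  # degenerate limit: with identical strong/weak levels the protocols
  # coincide and all populations are equal
  pp_eq <- symmetric4_population_params(
    influx = 2, inh_weight = 0.01, resilience_threshold = 0.05,
    survival_threshold = 0.4, steepness = 400,
    amplitudes = c(strong = 1, weak = 0.999))
  mc_eq <- mixture_comparison(pp_eq, "exact")
  expect_equal(mc_eq$p_mixture, mc_eq$p_pure_alt, tolerance = 1e-2)
  expect_equal(mc_eq$p_mixture, mc_eq$p_mixed_alt, tolerance = 1e-2)
})
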