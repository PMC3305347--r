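# shared helpers for the test suite; all fixtures are built in code

# hand-rolled Pearson used as an independent oracle for the metrics module
oracle_pearson <- function(a, b) {
  ac <- a - mean(a); bc <- b - mean(b)
  sum(ac * bc) / sqrt(sum(ac^2) * sum(bc^2))
}

# mean-field parameters for the symmetric-4 caricature in the regime used
# throughout the analytical tests
sym4_params <- function(resilience_threshold = 0.05, steepness = 100,
                        influx = 2, inh_weight = 0.01,
                        survival_threshold = 0.4, spontaneous = 0.1) {
  symmetric4_population_params(
    influx = influx, inh_weight = inh_weight,
    resilience_threshold = resilience_threshold,
    survival_threshold = survival_threshold,
    steepness = steepness, spontaneous = spontaneous)
}

# build a 4-mitral network with prescribed granule populations on the
# co-active pairs ({1,2}, {3,4}) and the four interfering pairs
sym4_network <- function(n_coactive, n_interfering, w = 0.01, s0 = 0.1) {
  net <- new_network(4L, connections = 2L, inh_weight = w, spontaneous = s0)
  pairs <- rbind(c(1L, 2L), c(3L, 4L), c(1L, 3L), c(1L, 4L),
                 c(2L, 3L), c(2L, 4L))
  counts <- c(n_coactive, n_coactive, rep(n_interfering, 4L))
  exc <- pairs[rep(seq_len(6L), counts), , drop = FALSE]
  net$exc <- exc
  net$inh <- exc
  net$inh_w <- matrix(w, nrow(exc), 2L)
  net$birth_step <- rep(0L, nrow(exc))
  net$cohort <- rep(NA_character_, nrow(exc))
  net
}

# per-pair granule counts of a K = 2 network on 4 mitral cells
sym4_pair_counts <- function(net) {
  key <- paste(pmin(net$exc[, 1], net$exc[, 2]),
               pmax(net$exc[, 1], net$exc[, 2]))
  tab <- table(factor(key, levels = c("1 2", "3 4", "1 3", "1 4",
                                      "2 3", "2 4")))
  c(coactive = mean(tab[1:2]), interfering = mean(tab[3:6]))
}
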