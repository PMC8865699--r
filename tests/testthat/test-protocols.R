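test_that("overlap identities: perfect match, silence, chance level", {
  pat <- make_pattern(c(1, 3, 5), 10)
  # activity equals the pattern in one bin -> m = 1 exactly
  spikes <- data.frame(time_ms = c(2, 5, 8), neuron = c(1L, 3L, 5L))
  ov <- overlap(pat, spikes, bin_ms = 10, t_range_ms = c(0, 10))
  expect_equal(ov$m, 1, tolerance = 1e-12)
  # silence -> m = 0
  ov0 <- overlap(pat, spikes, bin_ms = 10, t_range_ms = c(100, 120))
  expect_equal(ov0$m, c(0, 0))
  # activity independent of the pattern with matching density -> E[m] = 0
  set.seed(3)
  n_bins <- 10000
  who <- lapply(seq_len(n_bins), function(b)
    sample.int(100, 30))  # density 0.3 = pattern sparseness
  spikes_rand <- data.frame(
    time_ms = rep((seq_len(n_bins) - 0.5) * 10, each = 30),
    neuron = unlist(who))
  pat2 <- make_pattern(1:30, 100)
  ovr <- overlap(pat2, spikes_rand, bin_ms = 10,
                 t_range_ms = c(0, n_bins * 10))
  se <- sd(ovr$m) / sqrt(n_bins)
  expect_lt(abs(mean(ovr$m)), 3 * se)
  # duplicate spikes of one neuron in a bin count once
  dup <- data.frame(time_ms = c(2, 3, 4), neuron = c(1L, 1L, 1L))
  ovd <- overlap(pat, dup, bin_ms = 10, t_range_ms = c(0, 10))
  expect_equal(ovd$m, (1 - 0.3) / (10 * 0.3 * 0.7), tolerance = 1e-12)
  expect_error(make_pattern(1:10, 10), "non-trivial")
})

test_that("population rate estimator integrates exactly to the spike count", {
  set.seed(8)
  spikes <- data.frame(time_ms = runif(5000, 0, 1000),
                       neuron = sample.int(50, 5000, TRUE))
  pr <- population_rate(spikes, 50, bin_ms = 100, t_range_ms = c(0, 1000))
  expect_identical(sum(pr$count), 5000L)
  expect_equal(sum(pr$rate_hz) * 50 * 0.1, 5000)
})

test_that("exponential decay fit recovers a planted time constant", {
  t <- seq(0, 6000, by = 15)
  fit <- decay_time_constant(t, 0.1 + 0.05 * exp(-t / 3000))
  expect_equal(fit$tau_s, 3000, tolerance = 1e-3)
  expect_equal(fit$c_inf, 0.1, tolerance = 1e-6)
  # noisy series still recovered
  set.seed(1)
  y <- 0.1 + 0.05 * exp(-t / 3000) + rnorm(length(t), 0, 5e-4)
  expect_equal(decay_time_constant(t, y)$tau_s, 3000, tolerance = 0.1)
  expect_error(decay_time_constant(t, rep(0.1, length(t))), "decay")
})

test_that("gamma spike trains reproduce the requested rate and irregularity", {
  tr <- gamma_spike_train(50, 0.7, 2000, seed = 4)
  isi <- diff(tr)
  expect_gt(length(isi), 9e4)
  expect_equal(sd(isi) / mean(isi), 0.7, tolerance = 0.01)
  expect_equal(length(tr) / 2000, 50, tolerance = 0.02)
  # cv = 1 is the Poisson limit: exponential ISIs (CV of 1 and the
  # memoryless quantile ratio)
  trp <- gamma_spike_train(50, 1, 2000, seed = 5)
  isip <- diff(trp)
  expect_equal(sd(isip) / mean(isip), 1, tolerance = 0.02)
  qr <- quantile(isip, 0.75) / quantile(isip, 0.25)
  expect_equal(unname(qr), log(4) / log(4 / 3), tolerance = 0.1)
  expect_error(gamma_spike_train(10, 2, 1), "cv")
})

test_that("calcium statistics of a filtered Gamma train match Campbell's theorem", {
  cv <- 0.7
  stats_th <- calcium_equilibrium_stats(8, cv, tau_ca_s = 10)
  expect_equal(stats_th$mean, 8)
  expect_equal(stats_th$var, cv^2 * 8 / 20, tolerance = 1e-12)
  tr <- gamma_spike_train(8, cv, 20000, seed = 6)
  ca <- filter_calcium(tr, tau_ca_s = 10, dt_ms = 20, duration_ms = 2e7)
  phi <- ca$phi_hz[ca$time_ms > 1e5]
  expect_equal(mean(phi), 8, tolerance = 0.05)
  expect_equal(var(phi), stats_th$var, tolerance = 0.1)
  # the Gamma-based Gaussian explains the trace better than the Poisson one
  ll_gamma <- sum(dnorm(phi, 8, sqrt(stats_th$var), log = TRUE))
  ll_pois <- sum(dnorm(phi, 8, sqrt(1 * 8 / 20), log = TRUE))
  expect_gt(ll_gamma, ll_pois)
})

test_that("protocol construction validates ensembles and multipliers", {
  expect_error(episodes(c(1, -1)), "positive")
  expect_error(episodes(1, list(c(A = -0.5))), "non-negative")
  ens <- make_ensembles(100, c(A = 0.1, B = 0.1), seed = 1)
  expect_length(intersect(ens$A, ens$B), 0)
  expect_length(ens$A, 10)
  expect_error(engramnet:::ensemble_groups(100, 10, list(A = 1:5, B = 4:8)),
               "disjoint")
  net <- tiny_net()
  expect_error(run_network(net, episodes(1, list(c(ghost = 2)))),
               "undefined ensemble")
})

test_that("replaying a protocol with the same seeds is bit-reproducible", {
  net <- scaled_network(100, 25, seed = 7,
                        plasticity = plasticity_params(tau_ca_s = 1,
                                                       beta_a = 0.4,
                                                       beta_d = 0.4,
                                                       delta_t_s_ms = 10))
  ens <- make_ensembles(100, c(E1 = 0.1), seed = 2)
  proto <- episodes(c(2, 2), list(c(E1 = 1.4), c()), plastic = TRUE)
  r1 <- run_network(net, proto, ens, dt_ms = 0.5,
                    seeds = list(drive = 4, rewire = 5),
                    record = list(conn_every_s = 1))
  r2 <- run_network(net, proto, ens, dt_ms = 0.5,
                    seeds = list(drive = 4, rewire = 5),
                    record = list(conn_every_s = 1))
  expect_identical(r1$conn_series, r2$conn_series)
  expect_identical(r1$net$conn$ee[, ], r2$net$conn$ee[, ])
})

test_that("grown network matches the mean-field equilibrium in-degree", {
  g <- grown_scaled_net()
  expect_true(g$converged)
  expect_lt(abs(mean(g$net$state$phi) - 8) / 8, 0.05)
  k_pred <- equilibrium_indegree(8, meanfield_model())$k
  expect_lt(abs(mean(g$k_in) - k_pred) / k_pred, 0.05)
  # zero growth time leaves the EE block empty
  fresh <- scaled_network(100, 25, seed = 1)
  g0 <- grow_network(fresh, t_growth_s = 0)
  expect_identical(nrow(g0$net$conn$ee), 0L)
})

test_that("repeated stimulation strengthens the engram cycle after cycle", {
  enc <- encoded_net()
  cs <- subset(enc$conn_series, pre == "E1" & post == "E1")
  # connectivity at the end of each 300 s cycle increases strictly
  ends <- vapply(c(300, 600, 900), function(t)
    cs$cbar[which.min(abs(cs$time_s - t))], numeric(1))
  baseline <- cs$cbar[1]
  expect_true(all(diff(c(baseline, ends)) > 0))
  # within-engram exceeds engram-to-rest and rest-to-rest connectivity
  at_end <- function(p1, p2) {
    s <- enc$conn_series[enc$conn_series$pre == p1 &
                           enc$conn_series$post == p2, ]
    s$cbar[which.max(s$time_s)]
  }
  expect_gt(at_end("E1", "E1"), at_end("E1", "rest"))
  expect_gt(at_end("E1", "E1"), at_end("rest", "rest"))
})

test_that("encoded engrams perform pattern completion and drive a readout", {
  enc <- encoded_net()
  engram <- enc$net$ensembles$E1
  net <- enc$net
  # partial stimulation recruits the non-stimulated engram members
  pc <- pattern_completion_curve(net, engram, fractions = c(0.5, 1),
                                 n_draws = 2, stim_s = 4, dt_ms = 0.5,
                                 seed = 9)
  m_by_f <- tapply(pc$mean_overlap, pc$fraction, mean)
  expect_gt(m_by_f[["1"]], m_by_f[["0.5"]])
  # the curve lies above the one of an unstructured (random-ensemble)
  # pattern of the same size at every fraction
  set.seed(33)
  rnd_pat <- sample(setdiff(seq_len(1000), engram), length(engram))
  pc_ctl <- pattern_completion_curve(net, rnd_pat, fractions = c(0.5, 1),
                                     n_draws = 2, stim_s = 4, dt_ms = 0.5,
                                     seed = 9)
  m_ctl <- tapply(pc_ctl$mean_overlap, pc_ctl$fraction, mean)
  expect_gt(m_by_f[["0.5"]], m_ctl[["0.5"]])
  expect_gt(m_by_f[["1"]], m_ctl[["1"]])
  # stimulating half the engram raises the rate of the *non-stimulated*
  # members above the non-engram population
  set.seed(21)
  half <- sample(engram, length(engram) / 2)
  net$plasticity$enabled <- FALSE
  out <- run_network(net, episodes(4, list(c(S = 1.1)), plastic = FALSE),
                     ensembles = list(S = half), dt_ms = 0.5,
                     seeds = list(drive = 41, rewire = 1))
  rates <- out$episode_rates_hz[, 1]
  r_nonstim <- mean(rates[setdiff(engram, half)])
  r_outside <- mean(rates[setdiff(seq_len(1000), engram)])
  expect_gt(r_nonstim, r_outside)
  # a readout sampling 9% of the network fires more when the encoded
  # engram is stimulated than for a size-matched random ensemble
  ro <- attach_readout(net, 0.09, seed = 3)
  rnd <- setdiff(seq_len(1000), engram)[seq_along(engram)]
  proto <- episodes(rep(c(1, 4), 2),
                    list(c(E1 = 1.1), c(), c(R = 1.1), c()),
                    plastic = FALSE)
  outr <- run_network(net, proto, ensembles = list(E1 = engram, R = rnd),
                      dt_ms = 0.5, seeds = list(drive = 43, rewire = 1),
                      readouts = ro)
  ro_rates <- outr$episode_rates_hz[1251, ]
  expect_gt(ro_rates[1], ro_rates[3])
  # a readout with no sampled inputs and no drive anywhere stays silent
  silent <- run_network(net,
                        episodes(1, list(c(rest = 0, E1 = 0)),
                                 plastic = FALSE),
                        ensembles = list(E1 = engram), dt_ms = 0.5,
                        seeds = list(drive = 44, rewire = 1),
                        readouts = list(cbind(pre = integer(0),
                                              count = integer(0))),
                        init_v = rep(0, 1251))
  expect_identical(nrow(silent$readout_spikes), 0L)
})
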