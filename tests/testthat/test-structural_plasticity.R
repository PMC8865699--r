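test_that("calcium trace follows the exact low-pass update", {
  # closed-form decay over one time constant
  expect_equal(update_calcium(8, 0, 10, 10), 8 / exp(1), tolerance = 1e-12)
  # impulse response: one spike adds exactly 1/tau_Ca
  expect_equal(update_calcium(0, 1, 1e-9, 10) , 0.1, tolerance = 1e-6)
  # stationary mean of a filtered Poisson train equals the rate
  train <- gamma_spike_train(8, 1, 600, seed = 2)
  tr <- filter_calcium(train, tau_ca_s = 10, dt_ms = 5, duration_ms = 6e5)
  phi <- tr$phi_hz[tr$time_ms > 1e5]  # discard filter transient
  expect_lt(abs(mean(phi) - 8), 3 * sd(phi) / sqrt(length(phi) / 4000))
})

test_that("element counters integrate the homeostatic drive", {
  pl <- plasticity_params(beta_a = 2, beta_d = 2, nu_target_hz = 8)
  # at the set-point nothing moves
  up <- update_elements(5, 7, phi = 8, dt_s = 1, pl)
  expect_equal(up$a, 5)
  expect_equal(up$d, 7)
  # phi = 0: growth nu/beta per second
  up <- update_elements(0, 0, phi = 0, dt_s = 1, pl)
  expect_equal(up$a, 4)
  expect_equal(up$d, 4)
  # floored at zero
  up <- update_elements(0.5, 0.5, phi = 20, dt_s = 1, pl)
  expect_equal(up$a, 0)
  expect_equal(up$d, 0)
})

test_that("rewiring fixed point: no free and no negative elements leaves wiring unchanged", {
  ee <- matrix(c(1L, 2L, 2L, 2L, 1L, 1L), 2, 3, byrow = TRUE)
  # counters equal to the degrees exactly
  res <- rewire_step(ee, 3, a = c(2, 1, 0), d = c(1, 2, 0), seed = 5)
  expect_equal(res$ee[order(res$ee[, 1]), ], ee[order(ee[, 1]), ],
               ignore_attr = TRUE)
})

test_that("a single admissible pairing creates exactly that contact", {
  res <- rewire_step(matrix(integer(), 0, 3), 2, a = c(1, 0), d = c(0, 1),
                     seed = 3)
  expect_equal(unname(res$ee), matrix(c(1L, 2L, 1L), 1, 3))
  expect_equal(res$k_out, c(1L, 0L))
  expect_equal(res$k_in, c(0L, 1L))
})

test_that("deletion quotas are clipped to existing contacts and free bonded counterparts", {
  # neuron 1 has 2 outgoing contacts but its counter calls for 5 deletions
  ee <- matrix(c(1L, 2L, 2L), 1, 3)
  res <- rewire_step(ee, 3, a = c(0, 0, 0), d = c(0, 2, 0), seed = 1)
  expect_equal(nrow(res$ee), 0)
  expect_equal(res$k_out, c(0L, 0L, 0L))
})

test_that("rewiring bookkeeping: degrees recount, pairable pool exhausted, empty diagonal", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 6
    ee <- NULL
    # random starting graph
    for (pre in 1:n) {
      post <- sample(setdiff(1:n, pre), 2)
      ee <- rbind(ee, cbind(pre, post, sample(1:3, 2, replace = TRUE)))
    }
    storage.mode(ee) <- "integer"
    a <- runif(n, 0, 12)
    d <- runif(n, 0, 12)
    res <- rewire_step(ee, n, a, d, seed = seed * 13)
    # degrees consistent with the matrix
    k_in <- k_out <- integer(n)
    if (nrow(res$ee) > 0) {
      for (r in seq_len(nrow(res$ee))) {
        k_out[res$ee[r, 1]] <- k_out[res$ee[r, 1]] + res$ee[r, 3]
        k_in[res$ee[r, 2]] <- k_in[res$ee[r, 2]] + res$ee[r, 3]
      }
    }
    expect_equal(res$k_in, k_in)
    expect_equal(res$k_out, k_out)
    # no autapses
    if (nrow(res$ee) > 0) expect_true(all(res$ee[, 1] != res$ee[, 2]))
    # bonded elements never exceed the floored counters
    expect_true(all(k_out <= floor(a)))
    expect_true(all(k_in <= floor(d)))
    # all pairable pairs formed: one of the free pools is empty, or the
    # only leftovers are irreducible self-pairings on a single neuron
    a_plus <- pmax(floor(a) - k_out, 0)
    d_plus <- pmax(floor(d) - k_in, 0)
    owners <- union(which(a_plus > 0), which(d_plus > 0))
    expect_true(sum(a_plus) == 0 || sum(d_plus) == 0 ||
                  length(owners) == 1)
  }
})

test_that("pairing law on a 4-neuron toy: enumeration oracle vs hypergeometric closed form", {
  # free elements a+ = (2,0,1,0), d+ = (0,1,0,2)
  a_plus <- c(2, 0, 1, 0)
  d_plus <- c(0, 1, 0, 2)
  n_pair <- 3
  tot <- sum(a_plus) * sum(d_plus)
  # where the preferred-ensemble size is 1 the hypergeometric closed form
  # is the exact pairing law ...
  for (focal in list(c(3, 2), c(3, 4))) {
    pref <- a_plus[focal[1]] * d_plus[focal[2]]
    oracle <- enumerate_pairing(a_plus, d_plus, focal[1], focal[2])
    closed <- dhyper(seq_along(oracle) - 1, pref, tot - pref, n_pair)
    if (pref == 1)
      expect_equal(oracle, closed, tolerance = 1e-12)
  }
  # ... but with multiple free elements per neuron it is only a mean-field
  # approximation of uniform pairing: the exact law of pair 1 -> 4 forbids
  # c = 0 (both axonal elements of neuron 1 cannot avoid neuron 4's two
  # dendritic elements in a bijection of three)
  oracle14 <- enumerate_pairing(a_plus, d_plus, 1, 4)
  expect_equal(oracle14, c(0, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  closed14 <- dhyper(0:3, 4, tot - 4, n_pair)
  expect_gt(max(abs(oracle14 - closed14)), 0.1)
})

test_that("empirical rewiring draws match the exact enumeration law", {
  a_plus <- c(2, 0, 1, 0)
  d_plus <- c(0, 1, 0, 2)
  n_draw <- 20000
  tall <- matrix(0L, n_draw, 2)  # counts for pairs (1 -> 4) and (3 -> 2)
  for (k in seq_len(n_draw)) {
    res <- rewire_step(matrix(integer(), 0, 3), 4, a_plus, d_plus,
                       seed = 1000 + k)
    ee <- res$ee
    tall[k, 1] <- sum(ee[ee[, 1] == 1 & ee[, 2] == 4, 3])
    tall[k, 2] <- sum(ee[ee[, 1] == 3 & ee[, 2] == 2, 3])
  }
  for (j in 1:2) {
    focal <- list(c(1, 4), c(3, 2))[[j]]
    oracle <- enumerate_pairing(a_plus, d_plus, focal[1], focal[2])
    obs <- tabulate(tall[, j] + 1L, length(oracle))
    keep <- oracle > 0
    chi <- sum((obs[keep] - n_draw * oracle[keep])^2 /
                 (n_draw * oracle[keep]))
    p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(p, 0.01)
    expect_equal(sum(obs), n_draw)  # impossible counts never occur
  }
})

test_that("a frozen plastic run reproduces the pure spiking run exactly", {
  net <- scaled_network(100, 25, seed = 3)
  net$conn$ee <- matrix(c(1L, 2L, 2L, 4L, 7L, 1L), 2, 3)
  net$plasticity$enabled <- FALSE
  a <- run_interval(net, 1, plastic = TRUE, dt_ms = 0.5,
                    seeds = list(drive = 8, rewire = 9),
                    record = list(spike_windows_s = matrix(c(0, 1), 1),
                                  spikes_all = TRUE))
  b <- run_interval(net, 1, plastic = FALSE, dt_ms = 0.5,
                    seeds = list(drive = 8, rewire = 9),
                    record = list(spike_windows_s = matrix(c(0, 1), 1),
                                  spikes_all = TRUE))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$net$conn$ee[, ], b$net$conn$ee[, ])
})

test_that("homeostatic growth raises calcium toward the target and builds in-degree", {
  net <- scaled_network(200, 50, seed = 5,
                        plasticity = plasticity_params(
                          tau_ca_s = 1, beta_a = 0.4, beta_d = 0.4,
                          nu_target_hz = 8, delta_t_s_ms = 10))
  out <- run_interval(net, 60, plastic = TRUE, dt_ms = 0.5,
                      seeds = list(drive = 2, rewire = 3),
                      record = list(conn_every_s = 10))
  cb <- subset(out$conn_series, pre == "rest" & post == "rest")
  # connectivity grows monotonically during the growth phase
  expect_true(all(diff(cb$cbar) > 0))
  expect_gt(mean(out$net$state$phi), 4)
  expect_gt(mean(out$k_in), 300)
  # per-neuron creation is bounded by nu/beta per second
  expect_lt(max(out$k_in), 60 * 8 / 0.4)
})
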