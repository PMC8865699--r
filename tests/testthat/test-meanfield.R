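test_that("Siegert rate: limits, monotonicity and agreement with adaptive quadrature", {
  p <- lif_params()
  # deeply subthreshold input produces essentially no spikes
  expect_lt(siegert_rate(2, 1, p), 1e-12)
  # strong drift saturates at the refractory ceiling 1/t_ref = 500/s
  expect_gt(siegert_rate(2e5, 5, p), 490)
  expect_lt(siegert_rate(2e5, 5, p), 500)
  # and matches the deterministic drift solution at large mu
  mu_d <- 2000
  r_drift <- 1 / (2e-3 + 0.02 * log((mu_d - 10) / (mu_d - 20)))
  expect_equal(siegert_rate(mu_d, 5, p), r_drift, tolerance = 1e-4)
  # monotone in the mean drive
  mus <- seq(5, 40, by = 2.5)
  expect_true(all(diff(siegert_rate(mus, 5, p)) > 0))
  expect_error(siegert_rate(10, 0, p), "sigma")
  # independent evaluation of the same first-passage integral with R's
  # adaptive quadrature
  ref <- function(mu, sigma) {
    f <- function(u) erfcx_cpp(-u)
    v <- integrate(f, (p$v_r_mv - mu) / sigma, (p$v_th_mv - mu) / sigma,
                   rel.tol = 1e-12)$value
    1 / (2e-3 + 0.02 * sqrt(pi) * v)
  }
  for (mu in c(10, 14, 18, 22)) {
    expect_equal(siegert_rate(mu, 5.5, p), ref(mu, 5.5), tolerance = 1e-9)
  }
})

test_that("ISI CV: drift-dominated firing is regular, formula matches a simulated train", {
  p <- lif_params()
  expect_lt(cv_isi(40, 1.5, p), 0.25)
  # at fluctuation-dominated operating points CV approaches 1
  expect_gt(cv_isi(5, 8, p), 0.85)
  # formula vs empirical CV of a long simulated LIF spike train driven by
  # external Poisson input only (300 s)
  net <- new_network(1, 1, p, plasticity_params(enabled = FALSE), seed = 1)
  out <- run_interval(net, 300, plastic = FALSE, dt_ms = 0.1,
                      seeds = list(drive = 17, rewire = 1),
                      record = list(spike_windows_s = matrix(c(0, 300), 1)))
  isi <- diff(out$spikes$time_ms[out$spikes$neuron == 1])
  cv_emp <- sd(isi) / mean(isi)
  mu <- p$tau_m_ms * 1e-3 * p$j_mv * p$nu_ext_hz
  sg <- sqrt(p$tau_m_ms * 1e-3 * p$j_mv^2 * p$nu_ext_hz)
  expect_lt(abs(cv_isi(mu, sg, p) - cv_emp), 0.05)
})

test_that("rectified-Gaussian element rates obey the mean identity and limits", {
  set.seed(42)
  for (k in 1:50) {
    mu <- runif(1, -5, 5)
    sx <- runif(1, 0.01, 3)
    r <- element_rate_mean(mu, sx)
    expect_equal(r$creation - r$deletion, mu, tolerance = 1e-12)
  }
  # noise-free limit is the sharp rectifier
  expect_equal(element_rate_mean(2.5, 0)$creation, 2.5)
  expect_equal(element_rate_mean(-2.5, 0)$creation, 0)
  # at the set-point noise keeps rewiring alive at rate sigma_x/sqrt(2 pi)
  r0 <- element_rate_mean(0, 0.5)
  expect_equal(r0$creation, 0.5 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(r0$deletion, r0$creation)
})

test_that("input moments: external-only limit and weight scaling", {
  m <- mf_default()
  im0 <- input_moments(m, c(0, 0, 0), rep(0.1, 4))
  expect_equal(im0$mu, rep(m$tau_m_s * m$j_mv * m$nu_ext_hz, 3),
               tolerance = 1e-12)
  # doubling J doubles mu and quadruples the variance contributions
  m2 <- meanfield_model(params = lif_params(j_mv = 0.2))
  im2 <- input_moments(m2, c(0, 0, 0), rep(0.1, 4))
  expect_equal(im2$mu, 2 * im0$mu, tolerance = 1e-12)
  expect_equal(im2$sigma^2, 4 * im0$sigma^2, tolerance = 1e-12)
})

test_that("equilibrium in-degree solver is self-consistent and monotone in the target", {
  m <- mf_default()
  eq <- equilibrium_indegree(8, m)
  # the solver's operating point reproduces the target through the Siegert
  # transfer function
  expect_lt(abs(siegert_rate(eq$mu, eq$sigma, m$params) - 8), 1e-6)
  ks <- vapply(c(2, 4, 8, 16), function(nu) equilibrium_indegree(nu, m)$k,
               numeric(1))
  expect_true(all(diff(ks) > 0))
  expect_error(equilibrium_indegree(-1, m), "positive")
})

test_that("connectivity flow vanishes on the line attractor without noise", {
  m <- meanfield_model(eta = 0)
  k_star <- equilibrium_indegree(8, m)$k
  for (x in c(0.05, 0.0999, 0.2, 0.5)) {
    y <- line_attractor_point(x, m, k_star)
    dC <- connectivity_flow(m, y[1:2], y[3:6])
    expect_lt(max(abs(dC)), 1e-10)
  }
})

test_that("with spiking noise the flow points toward the most entropic configuration", {
  m <- mf_default()
  k_star <- equilibrium_indegree(8, m)$k
  cbar <- k_star / (m$n_e1 + m$n_e2)
  y <- line_attractor_point(0.2, m, k_star)  # engram stronger than uniform
  dC <- connectivity_flow(m, y[1:2], y[3:6])
  expect_lt(dC[1], 0)  # within-engram connectivity decays ...
  expect_gt(dC[2], 0)  # ... while cross connectivity recovers
  # and the uniform point is the fixed point
  y0 <- line_attractor_point(cbar, m, k_star)
  expect_lt(max(abs(connectivity_flow(m, y0[1:2], y0[3:6]))), 1e-12)
})

test_that("the R reference flow and the compiled integrator flow agree", {
  m <- mf_default()
  phi <- c(8.4, 7.9)
  conn <- c(0.13, 0.09, 0.11, 0.10)
  expect_equal(conn_flow_cpp(unclass(m), phi, conn),
               connectivity_flow(m, phi, conn), tolerance = 1e-12)
})

test_that("mean-field integration holds the grown equilibrium and shows dip-overshoot", {
  m <- mf_default()
  y0 <- meanfield_equilibrium(m)
  ep <- data.frame(duration_s = 20, mult_e1 = 1, mult_e2 = 1)
  tr <- integrate_model(m, ep, y0)
  expect_lt(max(abs(tr$c11 - y0["c11"])), 1e-6)
  expect_lt(max(abs(tr$r_e1 - 8)), 1e-3)
  # single-ensemble stimulation: connectivity dips during the stimulus and
  # overshoots above baseline after removal
  ep2 <- data.frame(duration_s = c(150, 450), mult_e1 = c(1.1, 1),
                    mult_e2 = 1)
  tr2 <- integrate_model(m, ep2, y0, record_every_s = 2)
  dip <- min(tr2$c11[tr2$time_s <= 150])
  peak <- max(tr2$c11[tr2$time_s > 150])
  expect_lt(dip, 0.95 * y0["c11"])
  expect_gt(peak, 1.05 * y0["c11"])
})

test_that("overly strong stimulation triggers the connectivity-rate limit cycle", {
  m <- mf_default()
  ep <- data.frame(duration_s = c(200, 1500), mult_e1 = c(1.25, 1),
                   mult_e2 = 1)
  tr <- integrate_model(m, ep, record_every_s = 1)
  cl <- classify_regime(tr, after_s = 200)
  expect_identical(cl$regime, "limit_cycle")
  expect_gte(cl$n_bursts, 2)
})
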