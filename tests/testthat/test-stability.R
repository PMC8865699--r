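test_that("line attractor points satisfy the fixed-degree constraints", {
  m <- mf_default()
  # direct substitution example: x = 0.2, K* = 1000
  y <- line_attractor_point(0.2, m, k_star = 1000)
  expect_equal(unname(y["c12"]), (1000 - 0.2 * 1000) / 9000,
               tolerance = 1e-12)
  expect_equal(unname(y["c12"]), 0.0888889, tolerance = 1e-6)
  # in-degree of both ensembles is exactly K* everywhere on the segment
  for (x in c(0.02, 0.1, 0.35, 0.8)) {
    y <- line_attractor_point(x, m, k_star = 1000)
    expect_equal(unname(y["c11"] * 1000 + y["c12"] * 9000), 1000,
                 tolerance = 1e-9)
    expect_equal(unname(y["c21"] * 1000 + y["c22"] * 9000), 1000,
                 tolerance = 1e-9)
    expect_true(all(y[3:6] >= 0))
  }
  # the uniform point has all four components equal
  yh <- line_attractor_point(0.1, m, k_star = 1000)
  expect_equal(unname(yh[3:6]), rep(0.1, 4), tolerance = 1e-12)
  expect_error(line_attractor_point(1.5, m, k_star = 1000), "admissible")
  expect_error(line_attractor_point(-0.05, m, k_star = 1000), "admissible")
})

test_that("connectivity block: spectrum {0,0,0,lambda1}, slow eigenvector, analytic match", {
  m <- mf_default()
  op <- operating_point(m)
  jb <- build_jacobian(m)
  an <- analytic_connectivity_block(m, cbar = op$c)
  # finite-difference block matches the closed form entrywise
  expect_lt(max(abs(jb$J_c - an$J_c)) / max(abs(an$J_c)), 1e-6)
  ev <- eigen(jb$J_c)
  i1 <- which.max(abs(ev$values))
  lam1 <- Re(ev$values[i1])
  expect_lt(abs(lam1 - an$lambda1) / abs(an$lambda1), 1e-6)
  expect_lt(max(abs(ev$values[-i1])), 1e-10 * abs(lam1) + 1e-12)
  # eigenvector proportional to (1, -N1/N2, -N1/N2, (N1/N2)^2)
  v <- Re(ev$vectors[, i1])
  v <- v / v[1]
  expect_equal(v, an$v1, tolerance = 1e-6)
  # lambda1 equals the analytic assembly to high precision
  expect_equal(1 / abs(lam1),
               slow_mode_timescale(c_bar = op$c), tolerance = 1e-8)
})

test_that("full Jacobian spectrum stays in the left half plane over the parameter grid", {
  for (pars in list(c(0.03, 1), c(0.5, 10), c(2, 10), c(4, 32), c(0.4, 32))) {
    m <- meanfield_model(beta_a = pars[1], beta_d = pars[1],
                         tau_ca_s = pars[2])
    ev <- eigen(build_jacobian(m)$J, only.values = TRUE)$values
    expect_lte(max(Re(ev)), 1e-8)
  }
})

test_that("slow-mode timescale: parameter scalings", {
  t0 <- slow_mode_timescale()
  # linear in N_E * c
  expect_equal(slow_mode_timescale(n_e = 20000), 2 * t0, tolerance = 1e-12)
  expect_equal(slow_mode_timescale(c_bar = 0.2), 2 * t0, tolerance = 1e-12)
  # log-log slope versus tau_Ca equals +1/2
  taus <- c(4, 16)
  slope <- diff(log(vapply(taus, function(tc)
    slow_mode_timescale(tau_ca_s = tc), numeric(1)))) / diff(log(taus))
  expect_equal(slope, 0.5, tolerance = 1e-10)
  # harmonic dependence on the growth parameters
  expect_equal(slow_mode_timescale(beta_a = 4, beta_d = 4), 2 * t0,
               tolerance = 1e-12)
})

test_that("oscillation boundary: linear in beta_d, oscillatory-but-stable regime", {
  m <- mf_default()
  op <- operating_point(m)
  # beta_d = 2, tau_Ca = 10 s lies in the weakly oscillatory regime:
  # complex eigenvalues with negative real part
  ev <- top_eig <- eigen(reduced_jacobian(m, 2, 10, op),
                         only.values = TRUE)$values
  ev <- ev[order(Re(ev), decreasing = TRUE)][1:2]
  expect_gt(abs(Im(ev[1])), 1e-6)
  expect_lt(max(Re(ev)), 0)
  # small tau_Ca: no oscillations
  ev2 <- eigen(reduced_jacobian(m, 2, 1, op), only.values = TRUE)$values
  ev2 <- ev2[order(Re(ev2), decreasing = TRUE)][1:2]
  expect_lt(abs(Im(ev2[1])), 1e-9)
  ob <- oscillation_boundary(c(1, 2), m, tol_s = 5e-3)
  expect_true(all(ob$max_re <= 0))
  # boundary scales linearly: tau(2)/tau(1) = 2
  expect_equal(ob$tau_ca_s[2] / ob$tau_ca_s[1], 2, tolerance = 0.05)
})

test_that("critical connectivity: limit and determinant sign change on the line", {
  m <- mf_default()
  op <- operating_point(m)
  cc <- critical_connectivity(m, op)
  expect_gt(cc, m$eps)
  # j_E -> infinity limit: c_crit -> eps
  op_inf <- op
  op_inf$j_ee <- 1e9
  expect_equal(critical_connectivity(m, op_inf), m$eps, tolerance = 1e-6)
  op_neg <- op
  op_neg$j_ee <- -1e-3
  expect_identical(critical_connectivity(m, op_neg), Inf)
  # det(J_r) changes sign exactly at the returned connectivity (the second
  # rate eigenvalue crosses zero there, so the product of the eigenvalues
  # goes from negative to positive)
  k_star <- equilibrium_indegree(8, m)$k
  det_at <- function(x) {
    y <- line_attractor_point(x, m, k_star)
    det(build_jacobian(m, y, op)$J_r)
  }
  expect_lt(det_at(cc - 0.02), 0)
  expect_gt(det_at(cc + 0.02), 0)
  root <- uniroot(det_at, c(m$eps, 0.9))$root
  expect_equal(root, cc, tolerance = 1e-3)
})

test_that("turnover ratio: noise-free limit, 1/beta scaling, decreasing in tau_Ca", {
  expect_identical(turnover_ratio(eta = 0), 0)
  t1 <- turnover_ratio(beta_a = 1, beta_d = 1)
  t2 <- turnover_ratio(beta_a = 2, beta_d = 2)
  expect_equal(t1 / t2, 2, tolerance = 1e-12)
  tors <- vapply(c(2, 8, 32), function(tc) turnover_ratio(tau_ca_s = tc),
                 numeric(1))
  expect_true(all(diff(tors) < 0))
})

test_that("stationary hyperplane dimension is (n_E - 1)^2 and the flow vanishes on it", {
  expect_identical(stationary_hyperplane_dim(c(1000, 9000)), 1L)
  expect_identical(stationary_hyperplane_dim(c(1000, 2000, 7000)), 4L)
  expect_identical(stationary_hyperplane_dim(c(500, 500, 1000, 8000)), 9L)
  # deterministic flow vanishes for any degree-preserving configuration
  sizes <- c(1000, 2000, 7000)
  nu <- 8
  base <- matrix(0.1, 3, 3)
  # degree-preserving perturbation: +d on (1,1) compensated within rows/cols
  d <- 0.02
  pert <- base
  pert[1, 1] <- pert[1, 1] + d
  pert[1, 2] <- pert[1, 2] - d * sizes[1] / sizes[2]
  pert[2, 1] <- pert[2, 1] - d * sizes[1] / sizes[2]
  pert[2, 2] <- pert[2, 2] + d * (sizes[1] / sizes[2])^2
  dC <- connectivity_flow_n(sizes, rep(nu, 3), pert, nu, 2, 2, 10, eta = 0)
  expect_lt(max(abs(dC)), 1e-12)
})
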