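# H1/CG solver: dense-matrix oracle, trivial minimizers, operator symmetry
# and positive semidefiniteness, residual monotonicity, and the
# large-data-weight limit.

test_that("CG matches a dense direct solve of the normal equations", {
  set.seed(61)
  d <- c(16, 16, 1)
  ph <- tiny_phantom(grid = d, n_coils = 1)
  u_hat <- ph$m_mag * exp(1i * ph$phi0) + 0.05
  coils <- array(1 + 0i, c(d, 1))
  mask <- poly_density_pattern(16, 1, p = 3, target_r = 2, seed = 2)
  phi <- 0.3 + 0.2 * outer(sin(seq(0, pi, length.out = 16)),
                           cos(seq(0, pi, length.out = 16)))
  v_true <- array(exp(-2i * phi), d)
  k <- step2_op(v_true, u_hat, coils, mask)
  mu <- 5e-4
  s <- solve_step2(k, u_hat, coils, mask, mu = mu, cg_tol = 1e-12,
                   cg_max_iters = 2000)

  # dense assembly of the same system, solved by direct factorization
  mu_eff <- mu * prod(d)
  Kd <- dense_matrix_from_op(function(e) step2_op(e, u_hat, coils, mask), d)
  Ld <- dense_matrix_from_op(laplacian_op, d)
  Hd <- mu_eff * Conj(t(Kd)) %*% Kd + Ld
  b <- mu_eff * as.vector(step2_op_adj(k, u_hat, coils, mask))
  v_dense <- solve(Hd, b)
  expect_lt(rel_err(as.vector(s$v), v_dense), 1e-6)
})

test_that("trivial cases: zero data and data-dominated consistent systems", {
  d <- c(12, 12, 2)
  coils <- array(1 + 0i, c(d, 1))
  ones <- array(1 + 0i, d)
  full <- matrix(1L, d[2], d[3])

  s0 <- solve_step2(array(0i, c(d, 1)), ones, coils, full, mu = 1)
  expect_equal(max(Mod(s0$v)), 0)
  expect_equal(s0$iters, 0L)

  # u_hat = 1, single coil, full sampling, consistent data, huge mu:
  # v recovers e^{-2i phi} pointwise
  xs <- seq(-1, 1, length.out = d[1])
  phi <- 0.4 + 0.3 * outer(xs^2, seq(-1, 1, length.out = d[2]))
  v_true <- array(exp(-2i * c(phi)), d)
  k <- step2_op(v_true, ones, coils, full)
  s <- solve_step2(k, ones, coils, full, mu = 1e4, cg_tol = 1e-12,
                   cg_max_iters = 1000)
  expect_lt(max(Mod(s$v - v_true)), 1e-3)

  expect_error(solve_step2(k, ones, coils, full, mu = 0), "positive")
})

test_that("the normal-equation operator is Hermitian positive semidefinite", {
  set.seed(62)
  d <- c(8, 8, 2)
  u_hat <- rand_cplx(d)
  coils <- rand_cplx(c(d, 2))
  mask <- rand_mask(8, 2)
  mu_eff <- 0.05 * prod(d)
  H <- function(v)
    mu_eff * step2_op_adj(step2_op(v, u_hat, coils, mask), u_hat, coils,
                          mask) + laplacian_op(v)
  for (i in 1:20) {
    x <- rand_cplx(d); y <- rand_cplx(d)
    ip1 <- sum(Conj(H(x)) * y)
    ip2 <- sum(Conj(x) * H(y))
    expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)
    expect_gte(Re(sum(Conj(x) * H(x))), 0)
  }
})

test_that("CG residuals converge with bounded excursions", {
  set.seed(63)
  d <- c(16, 16, 2)
  ph <- tiny_phantom(grid = d, n_coils = 2)
  u_hat <- ph$m_mag * exp(1i * ph$phi0) + 0.02
  mask <- block_pattern(16, 2, 8, 1)
  phi <- array(0.3, d)
  k <- step2_op(array(exp(-2i * 0.3), d), u_hat, ph$coils, mask)
  s <- solve_step2(k, u_hat, ph$coils, mask, mu = 5e-4, cg_tol = 1e-10,
                   cg_max_iters = 300)
  r <- s$resid_log
  # the 2-norm residual of CG is not pointwise monotone; its running minimum
  # is, excursions above it stay bounded, and the tolerance is reached
  expect_true(all(diff(cummin(r)) <= 0))
  expect_lt(max(r[-1] / cummin(r)[-length(r)]), 10)
  expect_lte(s$resid, 1e-10 * 1.0000001)
})

test_that("large mu recovers the doubled-phase field where signal exists", {
  ph <- tiny_phantom(grid = c(16, 16, 2), n_coils = 2)
  phi <- 53.4 * ph$b1_map^2
  u_hat <- ph$m_mag * exp(1i * (ph$phi0 + phi))
  v_true <- array(exp(-2i * phi), dim = ph$grid)
  full <- matrix(1L, 16, 2)
  k <- forward_op(u_hat * v_true, ph$coils, full)  # consistent neg-offset data
  s <- solve_step2(k, u_hat, ph$coils, full, mu = 1e5, cg_tol = 1e-12,
                   cg_max_iters = 2000)
  sup <- ph$support & (Mod(u_hat) > 0.1)
  expect_lt(max(Mod(s$v - v_true)[sup]), 1e-3)
})
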