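# Operator correctness: unitarity of the centered FFT, exactness of all
# adjoint pairs, Laplacian consistency, and the power-iteration norm.

test_that("centered FFT is unitary with DC at the centered index", {
  set.seed(11)
  x <- rand_cplx(c(8, 8, 8))
  expect_lt(abs(sum(Mod(fft_centered(x))^2) - sum(Mod(x)^2)),
            1e-12 * sum(Mod(x)^2))
  expect_lt(rel_err(ifft_centered(fft_centered(x)), x), 1e-12)

  # unit impulse at the grid center -> flat spectrum of modulus N^(-1/2)
  imp <- array(0i, c(8, 8, 8))
  imp[5, 5, 5] <- 1 + 0i
  sp <- fft_centered(imp)
  expect_equal(Mod(sp), array(8^(-3 / 2), c(8, 8, 8)), tolerance = 1e-12)

  # DC of a constant image lands at floor(N/2)+1 on each axis
  k <- fft_centered(array(1 + 0i, c(8, 6, 5)))
  idx <- which(Mod(k) > 1e-9, arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(5, 4, 3))

  # odd lengths: shifts remain exact inverses
  y <- rand_cplx(c(7, 5, 3))
  expect_identical(ifftshift_vol(fftshift_vol(y)), y)
  expect_lt(rel_err(ifft_centered(fft_centered(y)), y), 1e-12)
})

test_that("multi-coil forward/adjoint and step-2 operators pass dot-product tests", {
  set.seed(12)
  for (trial in 1:20) {
    d <- c(sample(4:8, 1), sample(4:8, 1), sample(1:4, 1))
    nc <- sample(1:3, 1)
    coils <- rand_cplx(c(d, nc))
    mask <- rand_mask(d[2], d[3])
    u <- rand_cplx(d)
    k <- rand_cplx(c(d, nc))
    ip1 <- sum(Conj(forward_op(u, coils, mask)) * k)
    ip2 <- sum(Conj(u) * adjoint_op(k, coils, mask))
    expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)

    u_hat <- rand_cplx(d)
    ip3 <- sum(Conj(step2_op(u, u_hat, coils, mask)) * k)
    ip4 <- sum(Conj(u) * step2_op_adj(k, u_hat, coils, mask))
    expect_lt(Mod(ip3 - ip4) / Mod(ip3), 1e-10)
  }
})

test_that("forward operator reduces correctly and zeroes off-pattern", {
  set.seed(13)
  d <- c(8, 8, 4)
  ones <- array(1 + 0i, d)
  full <- matrix(1L, d[2], d[3])
  u <- rand_cplx(d)
  # single coil of ones, full pattern: forward is just the FFT
  expect_equal(forward_op(u, ones, full)[, , , 1], fft_centered(u))
  expect_equal(adjoint_op(forward_op(u, ones, full), ones, full), u,
               tolerance = 1e-12)
  # zero image maps to zero data; masked entries are exactly zero
  coils <- rand_cplx(c(d, 2))
  mask <- rand_mask(d[2], d[3], 0.3)
  expect_equal(forward_op(array(0i, d), coils, mask),
               array(0i, c(d, 2)))
  k <- forward_op(u, coils, mask)
  off <- which(mask == 0)
  for (j in 1:2) {
    kj <- k[, , , j]
    dim(kj) <- c(d[1], d[2] * d[3])
    expect_true(all(kj[, off] == 0i))
  }
  # grid mismatch errors
  expect_error(forward_op(rand_cplx(c(4, 4, 2)), coils, mask), "mismatch")
})

test_that("step-2 operator reduces to the forward operator", {
  set.seed(14)
  d <- c(6, 6, 3)
  coils <- rand_cplx(c(d, 2))
  mask <- rand_mask(d[2], d[3])
  v <- rand_cplx(d)
  ones <- array(1 + 0i, d)
  expect_equal(step2_op(v, ones, coils, mask), forward_op(v, coils, mask))
  u_hat <- rand_cplx(d)
  expect_equal(step2_op(ones, u_hat, coils, mask),
               forward_op(u_hat, coils, mask))
})

test_that("derivative operators have exact adjoints and Neumann nullspace", {
  set.seed(15)
  for (trial in 1:20) {
    d <- c(sample(3:7, 1), sample(3:7, 1), sample(1:5, 1))
    f <- rand_cplx(d)
    w <- rand_cplx(c(d, 3))
    ip1 <- sum(Conj(grad_op(f)) * w)
    ip2 <- sum(Conj(f) * (-div_op(w)))
    expect_lt(Mod(ip1 - ip2) / max(Mod(ip1), 1e-300), 1e-12)

    e <- rand_cplx(c(d, 6))
    wgt <- c(1, 1, 1, 2, 2, 2)
    sg <- sym_grad_op(w)
    ip3 <- 0i
    for (i in 1:6) ip3 <- ip3 + wgt[i] * sum(Conj(sg[, , , i]) * e[, , , i])
    ip4 <- sum(Conj(w) * (-sym_div_op(e)))
    expect_lt(Mod(ip3 - ip4) / max(Mod(ip3), 1e-300), 1e-12)
  }
  cst <- array(3 + 2i, c(5, 4, 3))
  expect_true(all(grad_op(cst) == 0i))
  expect_true(all(laplacian_op(cst) == 0i))
})

test_that("laplacian equals the gradient normal operator on random fields", {
  set.seed(16)
  f <- rand_cplx(c(6, 5, 4))
  expect_identical(laplacian_op(f), -div_op(grad_op(f)))
  # self-adjoint and positive semidefinite
  g <- rand_cplx(c(6, 5, 4))
  ip1 <- sum(Conj(laplacian_op(f)) * g)
  ip2 <- sum(Conj(f) * laplacian_op(g))
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-12)
  expect_gte(Re(sum(Conj(f) * laplacian_op(f))), 0)
})

test_that("symmetrized gradient annihilates gradients of affine fields", {
  d <- c(8, 7, 5)
  x <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  aff <- (2 + 0i) + 1.5 * x - 0.7 * y
  w <- grad_op(aff)
  # interior second differences vanish; boundary rows are Neumann-clamped,
  # so restrict to the interior
  e <- sym_grad_op(w)
  inner <- e[2:(d[1] - 2), 2:(d[2] - 2), 2:(d[3] - 2), ]
  expect_lt(max(Mod(inner)), 1e-12)
})

test_that("power-iteration operator norm matches dense SVD within 1%", {
  set.seed(17)
  d <- c(8, 8, 1)
  coils <- rand_cplx(c(d, 1))
  mask <- rand_mask(8, 1, 0.6)
  A <- function(u) forward_op(u, coils, mask)
  AH <- function(k) adjoint_op(k, coils, mask)
  m <- dense_matrix_from_op(function(e) A(e), d)
  s_svd <- max(svd(m)$d)
  s_pow <- op_norm_power(A, AH, rand_cplx(d), iters = 100)
  expect_lt(abs(s_pow - s_svd) / s_svd, 0.01)
})
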