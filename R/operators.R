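# Linear operators: centered unitary FFTs, multi-coil masked Fourier
# forward/adjoint, and finite-difference derivative operators with exact
# adjoints. All image arrays are complex (Nx, Ny, Nz); coil dimension last.

#' @keywords internal
#' @noRd
.as_vol <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

# index vectors that rotate the DC sample between position 1 (FFT order)
# and position floor(n/2)+1 (centered order)
.fftshift_idx <- function(n) {
  f <- n - floor(n / 2)
  c(seq_len(floor(n / 2)) + f, seq_len(f))
}
.ifftshift_idx <- function(n) {
  f <- floor(n / 2)
  c(seq_len(n - f) + f, seq_len(f))
}

#' Shift the zero-frequency sample to the grid center
#'
#' `fftshift_vol()` moves the DC sample from index 1 (R's native FFT order) to
#' the centered index `floor(n/2)+1` on every axis; `ifftshift_vol()` is its
#' exact inverse (they differ for odd lengths).
#'
#' @param x A numeric or complex array with up to three dimensions.
#' @return An array of the same shape.
#' @export
fftshift_vol <- function(x) {
  x <- .as_vol(x)
  d <- dim(x)
  x[.fftshift_idx(d[1]), .fftshift_idx(d[2]), .fftshift_idx(d[3]), drop = FALSE]
}

#' @rdname fftshift_vol
#' @export
ifftshift_vol <- function(x) {
  x <- .as_vol(x)
  d <- dim(x)
  x[.ifftshift_idx(d[1]), .ifftshift_idx(d[2]), .ifftshift_idx(d[3]),
    drop = FALSE]
}

#' Centered unitary discrete Fourier transform of an image volume
#'
#' Orthonormal scaling (division by `sqrt(prod(dim))`) with pre/post shifting
#' so that both the image-domain and k-space-domain origins sit at the
#' centered index `floor(n/2)+1` on each axis. With this convention the
#' operator is unitary: `ifft_centered(fft_centered(x)) == x` to machine
#' precision and Parseval's identity holds exactly, which keeps the
#' regularization weights of the reconstruction stable across grid sizes.
#'
#' @param x Complex array (Nx, Ny, Nz); vectors and matrices are promoted by
#'   appending singleton dimensions.
#' @return Complex array of the same shape.
#' @export
fft_centered <- function(x) {
  x <- .as_vol(x)
  fftshift_vol(stats::fft(ifftshift_vol(x))) / sqrt(prod(dim(x)))
}

#' @rdname fft_centered
#' @export
ifft_centered <- function(x) {
  x <- .as_vol(x)
  fftshift_vol(stats::fft(ifftshift_vol(x), inverse = TRUE)) / sqrt(prod(dim(x)))
}

# expand a (Ny, Nz) phase-encode mask to an (Nx, Ny, Nz) 0/1 volume
#' @noRd
.mask_volume <- function(mask, nx) {
  mask <- as.matrix(mask)
  array(rep(as.numeric(mask), each = nx), dim = c(nx, nrow(mask), ncol(mask)))
}

#' @noRd
.check_grids <- function(u, coils, mask = NULL) {
  du <- dim(.as_vol(u))
  dc <- dim(coils)
  if (length(dc) == 3L) dc <- c(dc, 1L)
  if (!identical(du, dc[1:3]))
    stop("grid mismatch between image (", paste(du, collapse = "x"),
         ") and coil sensitivities (", paste(dc[1:3], collapse = "x"), ")")
  if (!is.null(mask) && !identical(dim(as.matrix(mask)), du[2:3]))
    stop("sampling mask must be (Ny, Nz) = (", du[2], ", ", du[3], ")")
  invisible(du)
}

#' @noRd
.coil_array <- function(coils) {
  if (length(dim(coils)) == 3L) dim(coils) <- c(dim(coils), 1L)
  coils
}

#' Multi-coil masked Fourier forward operator
#'
#' Per coil j computes `P * F(c_j * u)`: coil-sensitivity weighting, centered
#' unitary FFT along all three axes, then zeroing of all (ky, kz) phase
#' encodes outside the sampling mask (the readout axis kx is always fully
#' sampled).
#'
#' @param u Complex image volume (Nx, Ny, Nz).
#' @param coils Complex coil sensitivities (Nx, Ny, Nz, Nc).
#' @param mask Binary (Ny, Nz) sampling mask.
#' @return Complex k-space array (Nx, Ny, Nz, Nc), exactly zero off-pattern.
#' @seealso [adjoint_op()], [step2_op()]
#' @export
forward_op <- function(u, coils, mask) {
  coils <- .coil_array(coils)
  d <- .check_grids(u, coils, mask)
  nc <- dim(coils)[4]
  mv <- .mask_volume(mask, d[1])
  u <- .as_vol(u)
  k <- array(0i, dim = c(d, nc))
  for (j in seq_len(nc))
    k[, , , j] <- fft_centered(.slice4(coils, j) * u) * mv
  k
}

#' Adjoint of the multi-coil masked Fourier operator
#'
#' Computes `sum_j conj(c_j) * F^H(P * k_j)`, the exact adjoint of
#' [forward_op()] under the standard complex inner product.
#'
#' @param k Complex k-space array (Nx, Ny, Nz, Nc).
#' @param coils Complex coil sensitivities (Nx, Ny, Nz, Nc).
#' @param mask Binary (Ny, Nz) sampling mask.
#' @return Complex image volume (Nx, Ny, Nz).
#' @export
adjoint_op <- function(k, coils, mask) {
  coils <- .coil_array(coils)
  if (length(dim(k)) == 3L) dim(k) <- c(dim(k), 1L)
  d <- dim(k)[1:3]
  .check_grids(array(0i, d), coils, mask)
  nc <- dim(coils)[4]
  stopifnot(dim(k)[4] == nc)
  mv <- .mask_volume(mask, d[1])
  u <- array(0i, dim = d)
  for (j in seq_len(nc))
    u <- u + Conj(.slice4(coils, j)) * ifft_centered(.slice4(k, j) * mv)
  u
}

#' Fixed-morphology forward operator of the H1 phase step and its adjoint
#'
#' With the morphology image `u_hat` held fixed, the negative-offset data are
#' modeled as `K v = P * F(c_j * u_hat * v)` per coil, linear in the phase
#' field `v`. `step2_op()` applies K and `step2_op_adj()` its exact adjoint
#' `v = conj(u_hat) * sum_j conj(c_j) * F^H(P * k_j)`.
#'
#' @param v Complex image volume (the smooth doubled-phase field).
#' @param k Complex k-space array (Nx, Ny, Nz, Nc).
#' @param u_hat Fixed complex morphology image (Nx, Ny, Nz).
#' @param coils Complex coil sensitivities (Nx, Ny, Nz, Nc).
#' @param mask Binary (Ny, Nz) sampling mask.
#' @return `step2_op()`: k-space array; `step2_op_adj()`: image volume.
#' @export
step2_op <- function(v, u_hat, coils, mask) {
  forward_op(.as_vol(u_hat) * .as_vol(v), coils, mask)
}

#' @rdname step2_op
#' @export
step2_op_adj <- function(k, u_hat, coils, mask) {
  Conj(.as_vol(u_hat)) * adjoint_op(k, coils, mask)
}

# ---- finite-difference operators -------------------------------------------
# Forward differences with replicate (Neumann) boundary: the difference across
# the last index of an axis is zero. The divergences are defined as exact
# negative adjoints of the gradients so that the Laplacian used by the H1 step
# is literally grad-adjoint o grad.

#' @noRd
.dx_fwd <- function(f) {
  n <- dim(f)[1]
  if (n == 1L) return(f * 0)
  f[c(2:n, n), , , drop = FALSE] - f
}
#' @noRd
.dy_fwd <- function(f) {
  n <- dim(f)[2]
  if (n == 1L) return(f * 0)
  f[, c(2:n, n), , drop = FALSE] - f
}
#' @noRd
.dz_fwd <- function(f) {
  n <- dim(f)[3]
  if (n == 1L) return(f * 0)
  f[, , c(2:n, n), drop = FALSE] - f
}

# true adjoints of the forward differences: <Dx f, g> = <f, .dx_adj(g)>
# exactly under the Neumann rule above ((D^H g)_1 = -g_1,
# (D^H g)_i = g_{i-1} - g_i, (D^H g)_n = g_{n-1})
#' @noRd
.dx_adj <- function(g) {
  n <- dim(g)[1]
  if (n == 1L) return(g * 0)
  out <- g
  out[1, , ] <- -g[1, , ]
  if (n > 2L) out[2:(n - 1), , ] <- g[1:(n - 2), , ] - g[2:(n - 1), , ]
  out[n, , ] <- g[n - 1, , ]
  out
}
#' @noRd
.dy_adj <- function(g) {
  n <- dim(g)[2]
  if (n == 1L) return(g * 0)
  out <- g
  out[, 1, ] <- -g[, 1, ]
  if (n > 2L) out[, 2:(n - 1), ] <- g[, 1:(n - 2), ] - g[, 2:(n - 1), ]
  out[, n, ] <- g[, n - 1, ]
  out
}
#' @noRd
.dz_adj <- function(g) {
  n <- dim(g)[3]
  if (n == 1L) return(g * 0)
  out <- g
  out[, , 1] <- -g[, , 1]
  if (n > 2L) out[, , 2:(n - 1)] <- g[, , 1:(n - 2)] - g[, , 2:(n - 1)]
  out[, , n] <- g[, , n - 1]
  out
}

# extract component i of a stacked field without losing the 3D shape
#' @noRd
.slice4 <- function(a, i) {
  d <- dim(a)
  out <- a[, , , i, drop = FALSE]
  dim(out) <- d[1:3]
  out
}

#' Discrete gradient, divergence and Laplacian with Neumann boundary
#'
#' `grad_op()` applies forward differences with replicate (Neumann) boundary
#' handling along each axis and stacks the three components on a trailing
#' dimension. `div_op()` is defined as the exact negative adjoint of
#' `grad_op()`, and `laplacian_op(f)` is exactly
#' `-div_op(grad_op(f)) = grad^H grad f`, the positive semidefinite operator
#' appearing in the H1 normal equations. Constant fields are in the nullspace
#' of all three.
#'
#' @param f Complex or numeric image volume (Nx, Ny, Nz).
#' @param w Vector field (Nx, Ny, Nz, 3).
#' @return `grad_op()`: (Nx, Ny, Nz, 3) array; `div_op()`/`laplacian_op()`:
#'   (Nx, Ny, Nz) array.
#' @export
grad_op <- function(f) {
  f <- .as_vol(f)
  d <- dim(f)
  g <- array(if (is.complex(f)) 0i else 0, dim = c(d, 3L))
  g[, , , 1] <- .dx_fwd(f)
  g[, , , 2] <- .dy_fwd(f)
  g[, , , 3] <- .dz_fwd(f)
  g
}

#' @rdname grad_op
#' @export
div_op <- function(w) {
  stopifnot(length(dim(w)) == 4L, dim(w)[4] == 3L)
  -(.dx_adj(.slice4(w, 1)) + .dy_adj(.slice4(w, 2)) + .dz_adj(.slice4(w, 3)))
}

#' @rdname grad_op
#' @export
laplacian_op <- function(f) {
  -div_op(grad_op(f))
}

#' Symmetrized gradient of a vector field and its adjoint
#'
#' The second-order operator of TGV2: `sym_grad_op(w) = (J(w) + J(w)^T)/2`
#' with the same forward-difference/Neumann scheme as [grad_op()]. The six
#' unique tensor components are stored on the trailing dimension in the order
#' (xx, yy, zz, xy, xz, yz); off-diagonal components carry weight 2 in the
#' inner product and in the pointwise Frobenius norm, matching the symmetric
#' 3x3 tensor they represent. `sym_div_op()` is the exact negative adjoint
#' under that weighted pairing.
#'
#' @param w Vector field (Nx, Ny, Nz, 3).
#' @param e Symmetric tensor field (Nx, Ny, Nz, 6).
#' @return `sym_grad_op()`: (Nx, Ny, Nz, 6) array; `sym_div_op()`:
#'   (Nx, Ny, Nz, 3) array.
#' @export
sym_grad_op <- function(w) {
  stopifnot(length(dim(w)) == 4L, dim(w)[4] == 3L)
  d <- dim(w)[1:3]
  w1 <- .slice4(w, 1); w2 <- .slice4(w, 2); w3 <- .slice4(w, 3)
  e <- array(if (is.complex(w)) 0i else 0, dim = c(d, 6L))
  e[, , , 1] <- .dx_fwd(w1)
  e[, , , 2] <- .dy_fwd(w2)
  e[, , , 3] <- .dz_fwd(w3)
  e[, , , 4] <- 0.5 * (.dy_fwd(w1) + .dx_fwd(w2))
  e[, , , 5] <- 0.5 * (.dz_fwd(w1) + .dx_fwd(w3))
  e[, , , 6] <- 0.5 * (.dz_fwd(w2) + .dy_fwd(w3))
  e
}

#' @rdname sym_grad_op
#' @export
sym_div_op <- function(e) {
  stopifnot(length(dim(e)) == 4L, dim(e)[4] == 6L)
  d <- dim(e)[1:3]
  g <- function(i) .slice4(e, i)
  out <- array(if (is.complex(e)) 0i else 0, dim = c(d, 3L))
  # sym_div = -adjoint of sym_grad under the (1,1,1,2,2,2)-weighted pairing;
  # the weight 2 on off-diagonals cancels the 1/2 in the symmetrization
  out[, , , 1] <- -(.dx_adj(g(1)) + .dy_adj(g(4)) + .dz_adj(g(5)))
  out[, , , 2] <- -(.dy_adj(g(2)) + .dx_adj(g(4)) + .dz_adj(g(6)))
  out[, , , 3] <- -(.dz_adj(g(3)) + .dx_adj(g(5)) + .dy_adj(g(6)))
  out
}

#' Largest singular value of a linear operator by power iteration
#'
#' Runs power iteration on the normal operator `A^H A` starting from a fixed
#' random complex vector, returning an estimate of the operator 2-norm of A.
#' Used to set the primal-dual step sizes.
#'
#' @param apply_fn Function applying A to an array shaped like `x0`.
#' @param adjoint_fn Function applying A^H to the output of `apply_fn`.
#' @param x0 Starting array, or a list of arrays for operators on product
#'   spaces (defines the input space shape).
#' @param iters Number of power iterations (default 30).
#' @return Scalar estimate of `||A||_2`.
#' @export
op_norm_power <- function(apply_fn, adjoint_fn, x0, iters = 30) {
  gnorm <- function(x)
    if (is.list(x)) sqrt(sum(vapply(x, function(e) sum(Mod(e)^2), 0)))
    else sqrt(sum(Mod(x)^2))
  gscale <- function(x, s) if (is.list(x)) lapply(x, function(e) e * s)
    else x * s
  x <- x0
  nrm <- gnorm(x)
  if (nrm == 0) stop("zero starting vector")
  x <- gscale(x, 1 / nrm)
  s <- 1
  for (i in seq_len(iters)) {
    y <- adjoint_fn(apply_fn(x))
    nrm <- gnorm(y)
    if (nrm == 0) return(0)
    s <- sqrt(nrm)  # ||A^H A x|| -> sigma_max^2
    x <- gscale(y, 1 / nrm)
  }
  s
}
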