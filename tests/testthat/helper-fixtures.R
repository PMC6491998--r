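# Shared fixtures: random complex arrays, small phantoms/acquisitions, and a
# dense-matrix builder used by the operator and solver oracle tests.

rand_cplx <- function(d) {
  array(complex(real = stats::rnorm(prod(d)),
                imaginary = stats::rnorm(prod(d))), dim = d)
}

rand_mask <- function(ny, nz, frac = 0.5) {
  m <- matrix(stats::rbinom(ny * nz, 1, frac), ny, nz)
  m[floor(ny / 2) + 1, floor(nz / 2) + 1] <- 1L  # keep DC sampled
  m
}

# tiny phantom + paired acquisition used by several pipeline tests
tiny_phantom <- function(grid = c(32, 32, 4), n_coils = 4, seed = 1) {
  make_phantom(grid = grid, n_coils = n_coils, seed = seed)
}

# materialize a linear operator on image volumes of shape d as a dense
# (complex) matrix by applying it to the canonical basis
dense_matrix_from_op <- function(op, d) {
  n <- prod(d)
  m <- matrix(0i, n, n)
  for (i in seq_len(n)) {
    e <- array(0i, d)
    e[i] <- 1 + 0i
    m[, i] <- as.vector(op(e))
  }
  m
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / sqrt(sum(Mod(b)^2))
}

# shape-safe extraction of coil j from an (Nx, Ny, Nz, Nc) array
.subset_coil <- function(a, j) {
  d <- dim(a)
  out <- a[, , , j, drop = FALSE]
  dim(out) <- d[1:3]
  out
}
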