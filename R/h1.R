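# Step 2 of the two-step reconstruction: H1-regularized recovery of the
# smooth doubled-phase field v ~ exp(-2i*phi_BS) from the negative-offset
# data, with the morphology image u_hat held fixed:
#
#   v_hat = argmin_v  mu/2 sum_j ||P F(c_j u_hat v) - k_j||_2^2
#                     + 1/2 ||grad v||_2^2
#
# solved by conjugate gradients on the normal equations
#   (mu K^H K - Delta) v = mu K^H k_minus,
# where -Delta = grad^H grad is exactly the composition of the package's
# gradient with its adjoint (Neumann boundary), never a separate stencil.

#' H1-regularized phase-field reconstruction (step 2)
#'
#' Solves the normal equations of the H1 problem with plain conjugate
#' gradients. The system operator `mu K^H K + grad^H grad` is Hermitian
#' positive semidefinite and nonsingular wherever `u_hat * c` has support;
#' the Laplacian alone would be singular (constants in its nullspace), which
#' is why `mu > 0` is required.
#'
#' @param k Complex negative-offset k-space data (Nx, Ny, Nz, Nc), zero
#'   off-pattern.
#' @param u_hat Fixed complex morphology image from [solve_step1()].
#' @param coils Complex coil sensitivities (Nx, Ny, Nz, Nc).
#' @param mask Binary (Ny, Nz) sampling mask of the negative-offset scan.
#' @param mu Data fidelity weight (> 0); the tuned default is 5e-4. As in
#'   [solve_step1()], the squared data residual is accumulated in
#'   unnormalized-DFT units (effective weight `mu * Nx*Ny*Nz`).
#' @param cg_tol Relative residual stopping tolerance (default 1e-8).
#' @param cg_max_iters Maximum CG iterations (default 500).
#' @return A list with `v` (complex smooth field whose phase is minus the
#'   doubled Bloch-Siegert phase), `resid` (final relative residual),
#'   `iters`, `resid_log` and `converged`.
#' @export
solve_step2 <- function(k, u_hat, coils, mask, mu = 5e-4, cg_tol = 1e-8,
                        cg_max_iters = 500) {
  if (mu <= 0)
    stop("mu must be positive: with mu = 0 the system reduces to the ",
         "singular Laplacian (constants are in its nullspace)")
  coils <- .coil_array(coils)
  if (length(dim(k)) == 3L) dim(k) <- c(dim(k), 1L)
  u_hat <- .as_vol(u_hat)
  d <- dim(u_hat)

  mu_eff <- mu * prod(d)  # fidelity accumulated in unnormalized-DFT units
  H <- function(v)
    mu_eff * step2_op_adj(step2_op(v, u_hat, coils, mask), u_hat, coils, mask) +
      laplacian_op(v)
  b <- mu_eff * step2_op_adj(k, u_hat, coils, mask)

  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0)
    return(list(v = array(0i, d), resid = 0, iters = 0L,
                resid_log = numeric(0), converged = TRUE))

  v <- array(0i, d)
  r <- b              # residual b - H(0)
  p <- r
  rs <- sum(Mod(r)^2)
  resid_log <- sqrt(rs) / bnorm
  converged <- FALSE
  it_done <- 0L
  for (it in seq_len(cg_max_iters)) {
    Hp <- H(p)
    alpha <- rs / Re(sum(Conj(p) * Hp))
    v <- v + alpha * p
    r <- r - alpha * Hp
    rs_new <- sum(Mod(r)^2)
    resid_log <- c(resid_log, sqrt(rs_new) / bnorm)
    it_done <- it
    if (sqrt(rs_new) / bnorm <= cg_tol) { converged <- TRUE; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (!converged)
    warning("CG reached ", cg_max_iters, " iterations with relative residual ",
            signif(resid_log[length(resid_log)], 3))
  list(v = v, resid = resid_log[length(resid_log)], iters = it_done,
       resid_log = resid_log, converged = converged)
}
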