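# Restricted Hartree-Fock with DIIS, optionally coupled to the IEF-PCM
# reaction field (equilibrium solvation: surface charges are re-solved from
# the current density at every SCF iteration, and the polarization energy
# enters the total energy with the factor 1/2).

.sym_orth <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > 1e-10
  e$vectors[, keep] %*% (diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(e$vectors[, keep]))
}

# J and K builders from the full ERI tensor (kept as two reshaped matrices)
.fock_ops <- function(eri) {
  n <- dim(eri)[1]
  list(
    n = n,
    Jm = matrix(eri, n * n, n * n),
    Km = matrix(aperm(eri, c(1, 3, 2, 4)), n * n, n * n)
  )
}

.build_JK <- function(ops, D) {
  n <- ops$n
  J <- matrix(ops$Jm %*% as.vector(D), n, n)
  K <- matrix(ops$Km %*% as.vector(D), n, n)
  list(J = J, K = K)
}

#' Restricted Hartree-Fock
#'
#' Closed-shell RHF, optionally embedded in an IEF-PCM reaction field built
#' with [pcm_context()].  With a PCM context the converged result carries the
#' free energy in solution `G` (polarization counted with factor 1/2) and the
#' converged apparent surface charges.
#'
#' @param bs a `basis_set`.
#' @param pcm optional `pcm_context`.
#' @param conv energy convergence threshold (Hartree).
#' @param maxiter maximum SCF iterations.
#' @param ints,eri optionally precomputed [one_electron_integrals()] /
#'   [eri_integrals()] results (reused across calls during geometry scans).
#' @param D0 optional initial AO density (total, i.e. trace = n electrons).
#' @return An object of class `rhf_result`: orbital coefficients `C`
#'   (spherical AO basis), orbital energies `eps`, total energy `energy`
#'   (equals the free energy `G` in solution when `pcm` is given), density
#'   `D`, and PCM details (`q`, `e_pol`) when solvated.
#' @export
rhf <- function(bs, pcm = NULL, conv = 1e-9, maxiter = 150,
                ints = NULL, eri = NULL, D0 = NULL) {
  if (is.null(ints)) ints <- one_electron_integrals(bs)
  if (is.null(eri)) eri <- eri_integrals(bs)
  nel <- n_electrons(bs$mol)
  if (nel %% 2L != 0L) stop("RHF requires an even electron count")
  nocc <- nel %/% 2L
  n <- bs$nao
  S <- ints$S; h <- ints$H
  X <- .sym_orth(S)
  ops <- .fock_ops(eri)

  pcm_state <- NULL
  if (!is.null(pcm)) pcm_state <- pcm_precompute(pcm, bs)

  mo_from_fock <- function(F) {
    Fo <- crossprod(X, F %*% X)
    e <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(e$values)  # eigen() sorts decreasing; orbitals ascend
    C <- X %*% e$vectors[, ord, drop = FALSE]
    list(C = C, eps = e$values[ord])
  }

  if (is.null(D0)) {
    mo <- mo_from_fock(h)
    D <- 2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
  } else D <- D0

  diis_F <- list(); diis_e <- list()
  E_old <- Inf; E <- Inf
  e_pol <- 0; qsurf <- NULL
  for (it in seq_len(maxiter)) {
    jk <- .build_JK(ops, D)
    F <- h + jk$J - 0.5 * jk$K
    e_pol <- 0
    if (!is.null(pcm)) {
      sol <- pcm_field(pcm_state, D)
      F <- F + sol$V
      e_pol <- sol$e_pol
      qsurf <- sol$q
    }
    E <- 0.5 * sum(D * (h + h + jk$J - 0.5 * jk$K)) + ints$e_nuc + e_pol
    err <- F %*% D %*% S - S %*% D %*% F
    err <- crossprod(X, err %*% X)
    diis_F[[length(diis_F) + 1L]] <- F
    diis_e[[length(diis_e) + 1L]] <- err
    if (length(diis_F) > 8L) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m > 1L) {
      B <- matrix(0, m + 1L, m + 1L)
      for (i in 1:m) for (j in 1:m) B[i, j] <- sum(diis_e[[i]] * diis_e[[j]])
      B[m + 1L, 1:m] <- B[1:m, m + 1L] <- -1
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        F <- Reduce(`+`, Map(`*`, diis_F, cf))
      }
    }
    mo <- mo_from_fock(F)
    D_new <- 2 * tcrossprod(mo$C[, seq_len(nocc), drop = FALSE])
    dE <- abs(E - E_old)
    dD <- max(abs(D_new - D))
    D <- D_new
    E_old <- E
    if (dE < conv && dD < 1e-6 && it > 2L) {
      res <- list(C = mo$C, eps = mo$eps, energy = E, D = D, nocc = nocc,
                  converged = TRUE, iterations = it, bs = bs, ints = ints,
                  e_pol = e_pol, q = qsurf, pcm = pcm)
      class(res) <- "rhf_result"
      return(res)
    }
  }
  stop(sprintf("SCF failed to converge in %d iterations (last dE = %.3e)",
               maxiter, abs(E - E_old)))
}

#' @export
print.rhf_result <- function(x, ...) {
  kind <- if (is.null(x$pcm)) "gas phase" else "IEF-PCM"
  cat(sprintf("RHF (%s): E = %.10f Hartree, %d iterations\n",
              kind, x$energy, x$iterations))
  if (!is.null(x$pcm)) cat(sprintf("  polarization energy: %.8f Hartree\n", x$e_pol))
  invisible(x)
}
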