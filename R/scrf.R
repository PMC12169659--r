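# Self-consistent reaction-field ground state in a configuration subspace.
#
# Outer (macro) iterations alternate (i) a converged Davidson/dense solve of
# H0 + V_int in the subspace and (ii) a re-solve of the apparent surface
# charges from the relaxed total density.  The reported energy is the free
# energy G = <H0> + 1/2 q.phi (polarization counted half); the eigenvalue of
# the coupled operator counts the full coupling, so G = E_coupled - e_pol.

#' Solve the solvated ground-state SCRF problem in a subspace
#'
#' @param hmo an `mo_hamiltonian` carrying AO-basis blocks (from
#'   [build_active_hamiltonian()]).
#' @param subspace a `config_subspace`.
#' @param pcm a [pcm_config()], a precomputed `pcm_state`, or `NULL` for the
#'   gas phase.  `epsilon = 1` follows the gas-phase path bit-for-bit.
#' @param tol_E free-energy convergence threshold (Hartree).
#' @param tol_q convergence threshold on the maximum surface-charge change.
#' @param max_macro maximum SCRF macro-iterations.
#' @param damping linear damping factor on the surface charges (0 = off).
#' @param davidson_tol residual tolerance of the inner eigensolver.
#' @param v0 optional CI start vector.
#' @return A `solvated_result`: free energy `E` (Hartree), gas-phase subspace
#'   energy `E_gas`, polarization energy `e_pol`, CI vector `psi`,
#'   spin-orbital occupancies `occupancies`, surface charges `q`, the
#'   per-iteration `scrf_log` and a `converged` flag.
#' @export
solve_scrf_ground_state <- function(hmo, subspace, pcm = NULL, tol_E = 1e-8,
                                    tol_q = 1e-6, max_macro = 50, damping = 0,
                                    davidson_tol = 1e-8, v0 = NULL) {
  prob <- project_hamiltonian(hmo, subspace)
  gas <- ci_ground_state(prob, v0 = v0, tol = davidson_tol)
  occ_of <- function(vec) {
    g <- ci_rdm1(prob, vec)
    list(alpha = diag(g$alpha), beta = diag(g$beta), rdm = g)
  }
  if (is.null(pcm) || (inherits(pcm, "pcm_config") && pcm$epsilon == 1) ||
      (is.list(pcm) && !is.null(pcm$config) && pcm$config$epsilon == 1)) {
    oc <- occ_of(gas$vector)
    return(structure(list(
      E = gas$energy, E_gas = gas$energy, e_pol = 0, psi = gas$vector,
      occupancies = oc[c("alpha", "beta")], q = NULL,
      scrf_log = data.frame(iter = 0L, G = gas$energy, dq = 0),
      converged = gas$converged, subspace = subspace, d = subspace$d,
      solvated = FALSE), class = "solvated_result"))
  }
  state <- if (inherits(pcm, "pcm_config")) pcm_precompute(pcm, hmo$bs) else pcm
  Cc <- hmo$C_core; Ca <- hmo$C_act
  D_core <- if (ncol(Cc) > 0) 2 * tcrossprod(Cc) else matrix(0, nrow(Ca), nrow(Ca))
  psi <- gas$vector
  G_old <- Inf
  q_old <- NULL
  log_it <- list()
  converged <- FALSE
  fld <- NULL
  for (it in seq_len(max_macro)) {
    g1 <- ci_rdm1(prob, psi)
    D_tot <- D_core + Ca %*% g1$total %*% t(Ca)
    fld <- pcm_field(state, D_tot)
    q <- fld$q
    if (!is.null(q_old) && damping > 0) q <- (1 - damping) * q + damping * q_old
    # refold the (possibly damped) charges into the operator and energy
    Vao <- matrix(-(state$Tm %*% q), hmo$bs$nao, hmo$bs$nao)
    Vao <- (Vao + t(Vao)) / 2
    e_pol <- 0.5 * sum(q * fld$phi)
    V_act <- crossprod(Ca, Vao %*% Ca)
    e_shift <- sum(D_core * Vao) + sum(q * state$phi_nuc)
    .ci_set_h1(prob, hmo$h1 + (V_act + t(V_act)) / 2)
    sol <- ci_ground_state(prob, v0 = psi, tol = davidson_tol)
    psi <- sol$vector
    E_coupled <- sol$energy + e_shift
    G <- E_coupled - e_pol
    dq <- if (is.null(q_old)) Inf else max(abs(q - q_old))
    log_it[[it]] <- data.frame(iter = it, G = G, dq = dq)
    if (abs(G - G_old) < tol_E && dq < tol_q) { converged <- TRUE; G_old <- G; break }
    G_old <- G
    q_old <- q
  }
  if (!converged)
    stop(sprintf(paste0("SCRF did not converge in %d macro-iterations ",
                        "(last |dG| = %.2e); consider damping = 0.5"),
                 max_macro, abs(G - G_old)))
  oc <- occ_of(psi)
  structure(list(
    E = G_old, E_gas = gas$energy, e_pol = 0.5 * sum(fld$q * fld$phi),
    psi = psi, occupancies = oc[c("alpha", "beta")], q = fld$q,
    scrf_log = do.call(rbind, log_it), converged = TRUE,
    subspace = subspace, d = subspace$d, solvated = TRUE),
    class = "solvated_result")
}

#' @export
print.solvated_result <- function(x, ...) {
  cat(sprintf("solvated_result: E = %.10f Hartree (d = %s)%s\n", x$E,
              format(x$d, big.mark = ","),
              if (x$solvated) sprintf(", e_pol = %.8f", x$e_pol) else " [gas]"))
  invisible(x)
}

#' Select the lowest-energy batch
#'
#' The batch with minimal free energy `E` is the best ground-state
#' approximation; its solvation free energy is the reported one.  Ties are
#' broken by batch index (first wins).
#'
#' @param results list of `solvated_result`.
#' @return The winning `solvated_result`, with `$batch` set to its index.
#' @export
select_best_batch <- function(results) {
  if (length(results) == 0) stop("no batch results")
  Es <- vapply(results, function(r) r$E, 0)
  b <- which.min(Es)  # which.min returns the first minimum: ties -> lowest index
  out <- results[[b]]
  out$batch <- b
  out
}

#' Solvation free energy
#'
#' Default convention: `G_solv = G(solution) - E(gas)` with both energies from
#' the same method and subspace at the same geometry, converted to kcal/mol.
#' The pure polarization component (`e_pol`, also converted) is exposed as
#' well, since reference tabulations differ in which convention they report.
#'
#' @param solvated a `solvated_result` from a solvated run.
#' @param gas_energy gas-phase reference energy (Hartree) from the same
#'   method, subspace and geometry; defaults to the subspace gas energy
#'   stored in `solvated`.
#' @return List with `gsolv` (kcal/mol), `gsolv_polarization` (kcal/mol) and
#'   the Hartree values.
#' @export
gsolv <- function(solvated, gas_energy = solvated$E_gas) {
  if (!inherits(solvated, "solvated_result")) stop("need a solvated_result")
  dG <- solvated$E - gas_energy
  list(gsolv = dG * .const$hartree_kcal,
       gsolv_polarization = solvated$e_pol * .const$hartree_kcal,
       delta_hartree = dG, e_pol_hartree = solvated$e_pol)
}
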