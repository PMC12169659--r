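# Geometry optimization: BFGS on Cartesian coordinates with central-difference
# numerical gradients of the RHF (optionally IEF-PCM) energy.  The SCF at each
# displaced geometry is warm-started from the previous density, which keeps
# the finite-difference sweeps cheap and smooth.

#' RHF (optionally solvated) single-point energy
#'
#' @param mol a [molecule()].
#' @param basis basis-set name.
#' @param pcm optional [pcm_config()].
#' @param D0 optional AO density used as the SCF starting guess.
#' @return List with `energy` (Hartree), the converged `scf` result.
#' @export
single_point <- function(mol, basis = "cc-pvdz", pcm = NULL, D0 = NULL) {
  bs <- build_basis(mol, basis)
  scf <- rhf(bs, pcm = pcm, D0 = D0)
  list(energy = scf$energy, scf = scf)
}

#' Optimize a molecular geometry
#'
#' Minimizes the RHF (gas) or RHF IEF-PCM (solvated) energy with BFGS over
#' Cartesian coordinates; gradients are central finite differences.  Net
#' translational force is projected out.  Convergence requires the maximum
#' gradient component below `grad_tol` and the last energy change below
#' `e_tol`.
#'
#' @param mol starting [molecule()].
#' @param basis basis-set name.
#' @param pcm optional [pcm_config()] for solvated optimization.
#' @param grad_tol gradient convergence threshold (Hartree/Bohr).
#' @param e_tol energy-change convergence threshold (Hartree).
#' @param max_steps maximum BFGS steps.
#' @param h finite-difference displacement (Bohr).
#' @param max_disp trust cap on the step 2-norm (Bohr).
#' @param trace print per-step energies.
#' @return The optimized `molecule`, with attributes `energy`, `max_grad`,
#'   `steps`, `converged`.
#' @export
optimize_geometry <- function(mol, basis = "cc-pvdz", pcm = NULL,
                              grad_tol = 3e-4, e_tol = 1e-6, max_steps = 200,
                              h = 2e-3, max_disp = 0.35, trace = FALSE) {
  nat <- length(mol$elements)
  x <- as.vector(t(mol$coords)) / .const$bohr  # Bohr, atom-major triples
  Dlast <- NULL
  energy_at <- function(x) {
    m <- molecule(mol$elements, matrix(x, nat, 3, byrow = TRUE) * .const$bohr)
    sp <- single_point(m, basis, pcm, D0 = Dlast)
    Dlast <<- sp$scf$D
    sp$energy
  }
  grad_at <- function(x) {
    g <- numeric(length(x))
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      g[i] <- (energy_at(xp) - energy_at(xm)) / (2 * h)
    }
    # project out net translation
    gm <- matrix(g, nat, 3, byrow = TRUE)
    gm <- sweep(gm, 2, colMeans(gm))
    as.vector(t(gm))
  }
  E <- energy_at(x)
  g <- grad_at(x)
  B <- diag(length(x))  # inverse Hessian approximation
  dE <- 0  # a geometry already at the minimum returns after one gradient
  for (step in seq_len(max_steps)) {
    if (max(abs(g)) < grad_tol && abs(dE) < e_tol) {
      out <- molecule(mol$elements, matrix(x, nat, 3, byrow = TRUE) * .const$bohr)
      attr(out, "energy") <- E
      attr(out, "max_grad") <- max(abs(g))
      attr(out, "steps") <- step - 1L
      attr(out, "converged") <- TRUE
      return(out)
    }
    p <- -as.vector(B %*% g)
    pn <- sqrt(sum(p^2))
    if (pn > max_disp) p <- p * max_disp / pn
    alpha <- 1
    E_new <- energy_at(x + alpha * p)
    while (E_new > E + 1e-4 * alpha * sum(g * p) && alpha > 1e-3) {
      alpha <- alpha / 2
      E_new <- energy_at(x + alpha * p)
    }
    x_new <- x + alpha * p
    g_new <- grad_at(x_new)
    s <- x_new - x; y <- g_new - g
    sy <- sum(s * y)
    if (sy > 1e-10) {
      rho <- 1 / sy
      I <- diag(length(x))
      V <- I - rho * outer(s, y)
      B <- V %*% B %*% t(V) + rho * outer(s, s)
    }
    dE <- E_new - E
    if (trace)
      message(sprintf("  opt step %d: E = %.9f, dE = %+.2e, max|g| = %.2e, alpha = %.2f",
                      step, E_new, dE, max(abs(g_new)), alpha))
    x <- x_new; E <- E_new; g <- g_new
  }
  stop(sprintf("geometry optimization did not converge in %d steps (max|g| = %.3e Hartree/Bohr)",
               max_steps, max(abs(g))))
}
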