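# Determinant-CI layer: spin-inversion-closed configuration subspaces,
# projected Hamiltonians (Slater-Condon matrix elements equal the full-space
# values), Davidson diagonalization and one-particle densities.
#
# CI vectors are (N x N) matrices over (beta string, alpha string); the
# half-string set U is shared by both spins, so the determinant set is the
# spin-inversion-closed product S = U x U with d = |U|^2.

#' Spin-inversion-closed configuration subspace
#'
#' @param half_strings integer vector of occupation bitmasks over the active
#'   orbitals (bit p set = orbital p occupied; orbital 0 is the lowest).
#' @param norb number of active spatial orbitals.
#' @param n_alpha electrons per spin; every half-string must have this many
#'   bits set.
#' @return A `config_subspace` with sorted unique half-strings `U` and
#'   dimension `d = |U|^2`.
#' @export
configuration_subspace <- function(half_strings, norb, n_alpha) {
  u <- sort(unique(as.integer(half_strings)))
  pc <- vapply(u, function(x) sum(bitwAnd(bitwShiftR(x, 0:(norb - 1L)), 1L)), 0L)
  if (any(pc != n_alpha))
    stop("every half-string must have exactly n_alpha occupied orbitals")
  structure(list(U = u, norb = as.integer(norb), n_alpha = as.integer(n_alpha),
                 d = as.numeric(length(u))^2),
            class = "config_subspace")
}

#' @export
print.config_subspace <- function(x, ...) {
  cat(sprintf("config_subspace: |U| = %d half-strings over %d orbitals (%d per spin), d = %s\n",
              length(x$U), x$norb, x$n_alpha,
              format(x$d, big.mark = ",")))
  invisible(x)
}

#' Full determinant sector
#'
#' All half-strings of `n_alpha` electrons in `norb` orbitals; the resulting
#' subspace spans the complete (n_alpha, n_beta) Hilbert sector.
#'
#' @inheritParams configuration_subspace
#' @return A `config_subspace`.
#' @export
full_sector <- function(norb, n_alpha) {
  configuration_subspace(cpp_strings(norb, n_alpha), norb, n_alpha)
}

#' Project the Hamiltonian into a subspace
#'
#' Prepares the action of `P H P` (plus an optional one-electron solvent
#' operator folded into h1) on CI vectors over the subspace.  Matrix elements
#' between subspace determinants are the exact full-space Slater-Condon
#' values.
#'
#' @param hmo an `mo_hamiltonian` (see [build_active_hamiltonian()]).
#' @param subspace a `config_subspace`.
#' @param v_int optional one-electron operator (active MO basis) added to h1,
#'   e.g. the PCM reaction-field operator.
#' @return A `projected_problem`.
#' @export
project_hamiltonian <- function(hmo, subspace, v_int = NULL) {
  norb <- subspace$norb
  if (norb != hmo$n_orbitals) stop("subspace and Hamiltonian orbital counts differ")
  if (length(subspace$U) == 0) stop("empty subspace")
  h1 <- hmo$h1
  if (!is.null(v_int)) h1 <- h1 + v_int
  tab <- cpp_exc_tables(as.integer(subspace$U), norb)
  eri_v <- as.vector(hmo$h2)
  prob <- list2env(list(
    subspace = subspace, hmo = hmo, norb = norb, N = length(subspace$U),
    tab = tab, eri_v = eri_v,
    dval = cpp_doubles_val(tab, eri_v),
    occ = matrix(as.numeric(tab$occ), nrow = length(subspace$U)),
    h1 = h1, c1 = NULL, G = NULL, diag_mat = NULL
  ), parent = emptyenv())
  .ci_set_h1(prob, h1)
  class(prob) <- "projected_problem"
  prob
}

# update the one-electron part (SCRF macro-iterations re-use all tables)
.ci_set_h1 <- function(prob, h1) {
  prob$h1 <- h1
  prob$c1 <- cpp_singles_c1(prob$tab, as.vector(h1), prob$eri_v)
  n <- prob$norb
  eri <- array(prob$eri_v, rep(n, 4))
  # G[I, pq] = sum_{r occ in I} (pq|rr)
  Jpq <- matrix(0, n * n, n)
  for (r in 1:n) Jpq[, r] <- as.vector(eri[, , r, r])
  prob$G <- prob$occ %*% t(Jpq)
  # string diagonal: sum_p h_pp + 1/2 sum_{p,q} [(pp|qq) - (pq|qp)]
  A <- matrix(0, n, n); Jd <- matrix(0, n, n)
  for (p in 1:n) for (q in 1:n) {
    Jd[p, q] <- eri[p, p, q, q]
    A[p, q] <- eri[p, p, q, q] - eri[p, q, q, p]
  }
  dstr <- as.vector(prob$occ %*% diag(h1)) + 0.5 * rowSums((prob$occ %*% A) * prob$occ)
  prob$diag_mat <- outer(dstr, rep(1, prob$N)) + outer(rep(1, prob$N), dstr) +
    prob$occ %*% Jd %*% t(prob$occ)
  invisible(prob)
}

#' Apply the projected Hamiltonian to a CI vector
#'
#' @param prob a `projected_problem`.
#' @param C CI coefficient matrix (N x N), rows = beta strings, columns =
#'   alpha strings.
#' @return The matrix `H_S C` (electronic part; the core energy is added at
#'   the energy level, not here).
#' @export
ci_matvec <- function(prob, C) {
  # alpha-side singles/doubles plus the opposite-spin term ...
  r <- cpp_sigma_side(prob$tab, prob$c1, prob$dval, prob$G, prob$eri_v, C, 1L)
  # ... and the beta-side singles/doubles via the transposed vector
  rb <- cpp_sigma_side(prob$tab, prob$c1, prob$dval, prob$G, prob$eri_v, t(C), 0L)
  r$sigma + t(rb$sigma) + prob$diag_mat * C
}

#' Diagonal of the projected Hamiltonian
#'
#' @param prob a `projected_problem`.
#' @return Matrix (N x N) of determinant diagonal elements (electronic part).
#' @export
ci_hdiag <- function(prob) prob$diag_mat

#' Spin-resolved one-particle density matrices
#'
#' @param prob a `projected_problem`.
#' @param C normalized CI coefficient matrix.
#' @return List with `alpha` and `beta` density matrices over active orbitals
#'   and their `total` (alpha + beta).
#' @export
ci_rdm1 <- function(prob, C) {
  ga <- cpp_rdm1_side(prob$tab, C)
  gb <- cpp_rdm1_side(prob$tab, t(C))
  list(alpha = ga, beta = gb, total = ga + gb)
}

#' Davidson solver for the lowest eigenpair
#'
#' @param matvec function taking and returning a CI matrix.
#' @param hdiag diagonal matrix for preconditioning.
#' @param v0 start vector (matrix); defaults to a unit vector on the lowest
#'   diagonal element.
#' @param tol residual 2-norm convergence threshold.
#' @param max_iter maximum matrix applications.
#' @param max_space maximum Krylov subspace size before restart.
#' @return List with `value`, `vector`, `niter`, `converged`, `residual`.
#' @export
davidson <- function(matvec, hdiag, v0 = NULL, tol = 1e-8, max_iter = 200,
                     max_space = 20) {
  dims <- dim(hdiag)
  if (is.null(v0)) {
    v0 <- matrix(0, dims[1], dims[2])
    i0 <- which.min(hdiag)
    v0[i0] <- 1
  }
  v0 <- v0 / sqrt(sum(v0^2))
  V <- list(v0); W <- list(matvec(v0))
  theta <- sum(v0 * W[[1]])
  x <- v0
  nmv <- 1L
  for (it in seq_len(max_iter)) {
    m <- length(V)
    Hm <- matrix(0, m, m)
    for (i in 1:m) for (j in i:m) {
      Hm[i, j] <- Hm[j, i] <- sum(V[[i]] * W[[j]])
    }
    e <- eigen(Hm, symmetric = TRUE)
    k <- which.min(e$values)
    theta <- e$values[k]
    y <- e$vectors[, k]
    x <- y[1] * V[[1]]; Hx <- y[1] * W[[1]]
    if (m > 1) for (i in 2:m) { x <- x + y[i] * V[[i]]; Hx <- Hx + y[i] * W[[i]] }
    resid <- Hx - theta * x
    rn <- sqrt(sum(resid^2))
    if (rn < tol)
      return(list(value = theta, vector = x / sqrt(sum(x^2)), niter = nmv,
                  converged = TRUE, residual = rn))
    if (m >= max_space) { # restart with current best
      V <- list(x / sqrt(sum(x^2))); W <- list(Hx / sqrt(sum(x^2)))
      next
    }
    denom <- hdiag - theta
    denom[abs(denom) < 1e-8] <- 1e-8 * sign(denom[abs(denom) < 1e-8] + 1e-300)
    t_new <- -resid / denom
    # orthogonalize (twice for stability)
    for (rep in 1:2) for (v in V) t_new <- t_new - sum(v * t_new) * v
    tn <- sqrt(sum(t_new^2))
    if (tn < 1e-12)
      return(list(value = theta, vector = x / sqrt(sum(x^2)), niter = nmv,
                  converged = TRUE, residual = rn))
    t_new <- t_new / tn
    V[[length(V) + 1L]] <- t_new
    W[[length(W) + 1L]] <- matvec(t_new)
    nmv <- nmv + 1L
  }
  stop(sprintf("Davidson failed to converge in %d iterations (residual %.2e)",
               max_iter, sqrt(sum((matvec(x) - theta * x)^2))))
}

#' Solve a projected problem for its ground state
#'
#' Uses a dense eigensolve for small subspaces and Davidson otherwise.
#'
#' @param prob a `projected_problem`.
#' @param v0 optional start vector.
#' @param tol Davidson residual tolerance.
#' @param dense_cutoff dimension `d` below which a dense solve is used.
#' @return List with `energy` (electronic + core), `vector`, `niter`.
#' @export
ci_ground_state <- function(prob, v0 = NULL, tol = 1e-8, dense_cutoff = 4e4) {
  N <- prob$N
  if (N * N <= dense_cutoff) {
    H <- .ci_dense(prob)
    d <- N * N
    if (d <= 64) {
      e <- eigen(H, symmetric = TRUE)
      k <- which.min(e$values)
      vec <- matrix(e$vectors[, k], N, N)
      imax <- which.max(abs(vec))  # fix sign for determinism
      if (vec[imax] < 0) vec <- -vec
      return(list(energy = e$values[k] + prob$hmo$e_core, vector = vec,
                  niter = d, converged = TRUE))
    }
    r <- tryCatch(
      davidson(function(x) matrix(H %*% as.vector(x), N, N),
               matrix(diag(H), N, N), v0 = v0, tol = tol, max_space = 16),
      error = function(e) {
        ee <- eigen(H, symmetric = TRUE)
        k <- which.min(ee$values)
        list(value = ee$values[k], vector = matrix(ee$vectors[, k], N, N),
             niter = d, converged = TRUE)
      })
    vec <- r$vector
    imax <- which.max(abs(vec))
    if (vec[imax] < 0) vec <- -vec
    return(list(energy = r$value + prob$hmo$e_core, vector = vec,
                niter = r$niter, converged = r$converged))
  }
  r <- davidson(function(x) ci_matvec(prob, x), ci_hdiag(prob), v0 = v0, tol = tol)
  vec <- r$vector
  imax <- which.max(abs(vec))
  if (vec[imax] < 0) vec <- -vec
  list(energy = r$value + prob$hmo$e_core, vector = vec, niter = r$niter,
       converged = r$converged)
}

# dense projected Hamiltonian assembled directly from the excitation tables
# (production path for small d; the independent brute-force oracle used by
# the tests lives in the test helpers)
.ci_dense <- function(prob) {
  H <- cpp_dense_h(prob$tab, prob$c1, prob$dval, prob$G, prob$eri_v)
  diag(H) <- diag(H) + as.vector(prob$diag_mat)
  (H + t(H)) / 2
}

#' Write a configuration subspace as plain text
#'
#' One half-string per line (orbital 0 first), after `#` metadata lines;
#' round-trips through [read_subspace()].
#'
#' @param subspace a `config_subspace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_subspace <- function(subspace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# norb=%d", subspace$norb),
               sprintf("# n_alpha=%d", subspace$n_alpha)), con)
  bits <- vapply(subspace$U, function(m)
    paste(bitwAnd(bitwShiftR(m, seq_len(subspace$norb) - 1L), 1L), collapse = ""), "")
  writeLines(bits, con)
  invisible(path)
}

#' Read a configuration subspace dump
#'
#' @param path file written by [write_subspace()].
#' @return A `config_subspace`.
#' @export
read_subspace <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- trimws(ln[!startsWith(ln, "#")])
  body <- body[nzchar(body)]
  get <- function(key) as.integer(sub(paste0("^#\\s*", key, "="), "",
                                      grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)[1]))
  norb <- get("norb"); na <- get("n_alpha")
  u <- vapply(strsplit(body, ""), function(b)
    sum(bitwShiftL(1L, which(b == "1") - 1L)), 0L)
  configuration_subspace(as.integer(u), norb, na)
}
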