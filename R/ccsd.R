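# Closed-shell CCSD in the spin-orbital basis, over an active-space
# Hamiltonian (h1, h2, e_core).  Used to parametrize the LUCJ ansatz from
# gas-phase amplitudes; active spaces here are small (<= ~26 spin orbitals),
# so dense array contractions are adequate.  The reference determinant need
# not be canonical: off-diagonal Fock blocks enter the equations.

# minimal two-tensor einsum, e.g. .es("imae,mbej->ijab", t2, W);
# contracted indices are those shared by both inputs and absent from the
# output; batch indices are not supported (none are needed here)
.es <- function(spec, A, B) {
  parts <- strsplit(spec, "->", fixed = TRUE)[[1]]
  ins <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
  ia <- strsplit(ins[1], "")[[1]]
  ib <- strsplit(ins[2], "")[[1]]
  out <- if (length(parts) > 1 && nzchar(parts[2])) strsplit(parts[2], "")[[1]] else character(0)
  da <- dim(A); if (is.null(da)) da <- length(A)
  db <- dim(B); if (is.null(db)) db <- length(B)
  con <- setdiff(intersect(ia, ib), out)
  fa <- setdiff(ia, con); fb <- setdiff(ib, con)
  A2 <- aperm(A, c(match(fa, ia), match(con, ia)))
  B2 <- aperm(B, c(match(con, ib), match(fb, ib)))
  dfa <- da[match(fa, ia)]; dfb <- db[match(fb, ib)]; dco <- da[match(con, ia)]
  M <- matrix(A2, prod(dfa), prod(dco)) %*% matrix(B2, prod(dco), prod(dfb))
  if (length(out) == 0) return(sum(M))
  res <- array(M, c(dfa, dfb))
  aperm(res, match(out, c(fa, fb)))
}

# antisymmetrized spin-orbital integrals <pq||rs> (physicists) from spatial
# chemists' (pq|rs); spin orbital 2k-1 = spatial k alpha, 2k = spatial k beta
.spinorb_ints <- function(h1, h2) {
  n <- nrow(h1); m <- 2L * n
  sp <- rep(1:n, each = 2)
  sg <- rep(c(1L, 2L), n)
  hso <- matrix(0, m, m)
  for (p in 1:m) for (q in 1:m)
    if (sg[p] == sg[q]) hso[p, q] <- h1[sp[p], sp[q]]
  # <pq|rs> = (pr|qs) delta(s_p,s_r) delta(s_q,s_s)
  idx <- as.matrix(expand.grid(p = 1:m, q = 1:m, r = 1:m, s = 1:m))
  ok <- sg[idx[, 1]] == sg[idx[, 3]] & sg[idx[, 2]] == sg[idx[, 4]]
  v <- numeric(nrow(idx))
  v[ok] <- h2[cbind(sp[idx[ok, 1]], sp[idx[ok, 3]], sp[idx[ok, 2]], sp[idx[ok, 4]])]
  g <- array(v, c(m, m, m, m))
  g <- g - aperm(g, c(1, 2, 4, 3))
  list(h = hso, g = g, nso = m)
}

.Pij <- function(X) X - aperm(X, c(2, 1, 3, 4))
.Pab <- function(X) X - aperm(X, c(1, 2, 4, 3))

#' Closed-shell CCSD amplitudes for an active-space Hamiltonian
#'
#' Treats the lowest `n_alpha` active spatial orbitals as doubly occupied and
#' solves the spin-orbital CCSD equations with DIIS.
#'
#' @param hmo an `mo_hamiltonian`.
#' @param conv amplitude RMS convergence threshold.
#' @param max_iter maximum iterations.
#' @return A `ccsd_result`: correlation energy `e_corr`, total `energy`,
#'   spatial amplitudes `t1` (occ x vir) and `t2` (occ, occ, vir, vir;
#'   opposite-spin block, the RCCSD convention), convergence info.
#' @export
ccsd <- function(hmo, conv = 1e-8, max_iter = 120) {
  so <- .spinorb_ints(hmo$h1, hmo$h2)
  m <- so$nso
  nocc <- hmo$n_electrons
  if (nocc <= 0 || nocc >= m) stop("no correlation possible in this active space")
  o <- 1:nocc; v <- (nocc + 1):m
  no <- length(o); nv <- length(v)
  g <- so$g
  f <- so$h
  for (i in o) f <- f + g[, i, , i]
  fov <- f[o, v, drop = FALSE]
  fo_nd <- f[o, o]; diag(fo_nd) <- 0
  fv_nd <- f[v, v]; diag(fv_nd) <- 0
  eo <- diag(f)[o]; ev <- diag(f)[v]
  Dia <- outer(eo, ev, `-`)
  Dijab <- aperm(outer(outer(eo, eo, `+`), outer(ev, ev, `+`), `-`), c(1, 2, 3, 4))
  goovv <- g[o, o, v, v, drop = FALSE]
  t1 <- fov / Dia
  t2 <- goovv / Dijab
  e_corr <- function(t1, t2) {
    e <- .es("ia,ia->", fov, t1) + 0.25 * .es("ijab,ijab->", goovv, t2)
    e + 0.5 * sum(.es("ijab,ia->jb", goovv, t1) * t1)
  }
  amps <- list(); errs <- list()
  e_old <- Inf
  for (it in seq_len(max_iter)) {
    t1t1 <- .es("ia,jb->ijab", t1, t1)
    tau_t <- t2 + 0.5 * (t1t1 - aperm(t1t1, c(1, 2, 4, 3)))
    tau <- t2 + (t1t1 - aperm(t1t1, c(1, 2, 4, 3)))
    Fae <- fv_nd - 0.5 * .es("ma,me->ae", t1, fov) +
      .es("mf,mafe->ae", t1, g[o, v, v, v, drop = FALSE]) -
      0.5 * .es("mnaf,mnef->ae", tau_t, goovv)
    Fmi <- fo_nd + 0.5 * .es("ie,me->mi", t1, fov) +
      .es("ne,mnie->mi", t1, g[o, o, o, v, drop = FALSE]) +
      0.5 * .es("inef,mnef->mi", tau_t, goovv)
    Fme <- fov + .es("nf,mnef->me", t1, goovv)
    Wmnij <- g[o, o, o, o, drop = FALSE] +
      0.25 * .es("ijef,mnef->mnij", tau, goovv)
    PE <- .es("je,mnie->mnij", t1, g[o, o, o, v, drop = FALSE])
    Wmnij <- Wmnij + PE - aperm(PE, c(1, 2, 4, 3))
    Wabef <- g[v, v, v, v, drop = FALSE] +
      0.25 * .es("mnab,mnef->abef", tau, goovv)
    PM <- .es("mb,amef->abef", t1, g[v, o, v, v, drop = FALSE])
    Wabef <- Wabef - PM + aperm(PM, c(2, 1, 3, 4))
    Wmbej <- g[o, v, v, o, drop = FALSE] +
      .es("jf,mbef->mbej", t1, g[o, v, v, v, drop = FALSE]) -
      .es("nb,mnej->mbej", t1, g[o, o, v, o, drop = FALSE]) -
      .es("jnfb,mnef->mbej", 0.5 * t2 + .es("jf,nb->jnfb", t1, t1), goovv)
    # T1
    rhs1 <- fov + .es("ie,ae->ia", t1, Fae) - .es("ma,mi->ia", t1, Fmi) +
      .es("imae,me->ia", t2, Fme) - .es("nf,naif->ia", t1, g[o, v, o, v, drop = FALSE]) -
      0.5 * .es("imef,maef->ia", t2, g[o, v, v, v, drop = FALSE]) -
      0.5 * .es("mnae,nmei->ia", t2, g[o, o, v, o, drop = FALSE])
    t1n <- rhs1 / Dia
    # T2
    rhs2 <- goovv
    X <- .es("ijae,be->ijab", t2, Fae - 0.5 * .es("mb,me->be", t1, Fme))
    rhs2 <- rhs2 + X - aperm(X, c(1, 2, 4, 3))
    X <- .es("imab,mj->ijab", t2, Fmi + 0.5 * .es("je,me->mj", t1, Fme))
    rhs2 <- rhs2 - (X - aperm(X, c(2, 1, 3, 4)))
    rhs2 <- rhs2 + 0.5 * .es("mnab,mnij->ijab", tau, Wmnij) +
      0.5 * .es("ijef,abef->ijab", tau, Wabef)
    X <- .es("imae,mbej->ijab", t2, Wmbej) -
      .es("imea,mbej->ijab", .es("ie,ma->imea", t1, t1), g[o, v, v, o, drop = FALSE])
    rhs2 <- rhs2 + X - aperm(X, c(1, 2, 4, 3)) - aperm(X, c(2, 1, 3, 4)) +
      aperm(X, c(2, 1, 4, 3))
    X <- .es("ie,abej->ijab", t1, g[v, v, v, o, drop = FALSE])
    rhs2 <- rhs2 + X - aperm(X, c(2, 1, 3, 4))
    X <- .es("ma,mbij->ijab", t1, g[o, v, o, o, drop = FALSE])
    rhs2 <- rhs2 - (X - aperm(X, c(1, 2, 4, 3)))
    t2n <- rhs2 / Dijab
    # DIIS on stacked amplitudes
    amps[[length(amps) + 1L]] <- c(as.vector(t1n), as.vector(t2n))
    errs[[length(errs) + 1L]] <- c(as.vector(t1n - t1), as.vector(t2n - t2))
    if (length(amps) > 6L) { amps <- amps[-1]; errs <- errs[-1] }
    nd <- length(amps)
    if (nd > 1L) {
      B <- matrix(0, nd + 1L, nd + 1L)
      for (i in 1:nd) for (j in 1:nd) B[i, j] <- sum(errs[[i]] * errs[[j]])
      B[nd + 1L, 1:nd] <- B[1:nd, nd + 1L] <- -1
      cf <- tryCatch(solve(B, c(rep(0, nd), -1))[1:nd], error = function(e) NULL)
      if (!is.null(cf) && all(is.finite(cf))) {
        comb <- Reduce(`+`, Map(`*`, amps, cf))
        t1n <- array(comb[seq_len(no * nv)], c(no, nv))
        t2n <- array(comb[-seq_len(no * nv)], c(no, no, nv, nv))
      }
    }
    rms <- sqrt(mean(c(t1n - t1, t2n - t2)^2))
    t1 <- t1n; t2 <- t2n
    ec <- e_corr(t1, t2)
    if (rms < conv && abs(ec - e_old) < conv) {
      # spatial amplitudes: alpha-alpha block of t1, alpha-beta block of t2
      oa <- seq(1, 2 * (no %/% 2), by = 2)   # alpha occupied spin orbitals
      va <- seq(1, 2 * (nv %/% 2), by = 2)
      t1_sp <- t1[oa, va, drop = FALSE]
      t2_sp <- t2[oa, oa + 1, va, va + 1, drop = FALSE]
      return(structure(list(e_corr = ec, energy = ec + .ccsd_ref_energy(so, nocc, hmo$e_core),
                            t1 = t1_sp, t2 = t2_sp,
                            t1_so = t1, t2_so = t2, iterations = it,
                            converged = TRUE, n_occ = no %/% 2, n_vir = nv %/% 2),
                       class = "ccsd_result"))
    }
    e_old <- ec
  }
  stop(sprintf("CCSD failed to converge in %d iterations (last RMS %.2e)",
               max_iter, rms))
}

.ccsd_ref_energy <- function(so, nocc, e_core) {
  o <- 1:nocc
  e <- sum(diag(so$h)[o])
  for (i in o) for (j in o) e <- e + 0.5 * so$g[i, j, i, j]
  e + e_core
}

#' @export
print.ccsd_result <- function(x, ...) {
  cat(sprintf("CCSD: E = %.10f Hartree (E_corr = %.8f), %d iterations\n",
              x$energy, x$e_corr, x$iterations))
  invisible(x)
}
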