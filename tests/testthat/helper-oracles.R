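# Independent brute-force oracles and shared (memoized) small fixtures.
#
# The dense Hamiltonian oracle takes the operator-product route through the
# full Fock space (second-quantized operators applied bit-by-bit, then
# projection onto the subspace), entirely separate from the package's
# Slater-Condon string machinery.

# single-spin sector matrix of a+_p a_q over the given occupation strings
# (0-based orbitals); E_pq conserves particle number, so operator products
# close within the sector
.oracle_Epq_spin <- function(p, q, strs) {
  N <- length(strs)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    m <- strs[i]
    if (!bitwAnd(m, bitwShiftL(1L, q))) next
    m1 <- bitwXor(m, bitwShiftL(1L, q))
    s1 <- if (q == 0) 1 else (-1)^sum(bitwAnd(m, bitwShiftL(1L, 0:(q - 1))) > 0)
    if (bitwAnd(m1, bitwShiftL(1L, p))) next
    m2 <- bitwOr(m1, bitwShiftL(1L, p))
    s2 <- if (p == 0) 1 else (-1)^sum(bitwAnd(m1, bitwShiftL(1L, 0:(p - 1))) > 0)
    j <- match(m2, strs)
    A[j, i] <- s1 * s2
  }
  A
}

# dense many-body Hamiltonian over the subspace U x U (package layout:
# determinant index = beta + N * alpha, alpha slow), via the operator-product
# route H = sum h E_pq + 1/2 sum (pq|rs) [E_pq E_rs - delta_qr E_ps] applied
# to subspace basis vectors within the full fixed-particle-number sector
oracle_dense_h <- function(h1, eri, U, norb) {
  n_alpha <- sum(bitwAnd(bitwShiftR(U[1], 0:(norb - 1)), 1L))
  cmb <- utils::combn(0:(norb - 1), n_alpha)
  strs <- sort(as.integer(apply(cmb, 2, function(ix) sum(2^ix))))
  N <- length(strs)
  Id <- diag(N)
  Es <- lapply(1:norb, function(p) lapply(1:norb, function(q) {
    A <- .oracle_Epq_spin(p - 1L, q - 1L, strs)
    kronecker(A, Id) + kronecker(Id, A)     # alpha slow + beta fast
  }))
  nu <- length(U)
  d <- nu * nu
  # subspace basis vectors as columns in the sector product space
  idx <- integer(d)
  k <- 1L
  for (ia in 1:nu) for (ib in 1:nu) {
    idx[k] <- match(U[ib], strs) + N * (match(U[ia], strs) - 1L)
    k <- k + 1L
  }
  Phi <- matrix(0, N * N, d)
  Phi[cbind(idx, seq_len(d))] <- 1
  # effective one-body part carrying the -1/2 delta_qr E_ps contraction:
  # h_eff[p, s] = h1[p, s] - 1/2 sum_q (pq|qs)
  h_eff <- h1 - 0.5 * apply(eri, c(1, 4), function(blk) sum(diag(blk)))
  HPhi <- matrix(0, N * N, d)
  W <- vector("list", norb * norb)
  for (r in 1:norb) for (s in 1:norb)
    W[[(r - 1) * norb + s]] <- Es[[r]][[s]] %*% Phi
  for (p in 1:norb) for (q in 1:norb) {
    if (h_eff[p, q] != 0) HPhi <- HPhi + h_eff[p, q] * W[[(p - 1) * norb + q]]
    Tm <- 0
    for (r in 1:norb) for (s in 1:norb) {
      v <- eri[p, q, r, s]
      if (v != 0) Tm <- Tm + v * W[[(r - 1) * norb + s]]
    }
    if (!identical(Tm, 0)) HPhi <- HPhi + 0.5 * (Es[[p]][[q]] %*% Tm)
  }
  HPhi[idx, , drop = FALSE]
}

# dense sector matrix of a one-body generator sum_pq K[p,q] E_pq restricted
# to the fixed-particle-number sector strings (complex allowed)
oracle_sector_onebody <- function(K, strings, norb) {
  N <- length(strings)
  A <- matrix(0 + 0i, N, N)
  for (I in seq_len(N)) {
    s <- strings[I]
    for (q in 0:(norb - 1)) {
      if (!bitwAnd(s, bitwShiftL(1L, q))) next
      s1 <- bitwXor(s, bitwShiftL(1L, q))
      sq <- if (q == 0) 1 else (-1)^sum(bitwAnd(s, bitwShiftL(1L, 0:(q - 1))) > 0)
      for (p in 0:(norb - 1)) {
        if (bitwAnd(s1, bitwShiftL(1L, p))) next
        s2 <- bitwOr(s1, bitwShiftL(1L, p))
        sp <- if (p == 0) 1 else (-1)^sum(bitwAnd(s1, bitwShiftL(1L, 0:(p - 1))) > 0)
        J <- match(s2, strings)
        A[J, I] <- A[J, I] + K[p + 1, q + 1] * sq * sp
      }
    }
  }
  Id <- diag(N)
  kronecker(A, Id) + kronecker(Id, A)   # alpha slow (columns), beta fast
}

oracle_expm <- function(M) {
  e <- eigen(M)
  e$vectors %*% diag(exp(e$values), nrow = nrow(M)) %*% solve(e$vectors)
}

# ---- memoized fixtures ---------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

# H4 chain, STO-3G, (4e,4o): small gas-phase CI workhorse
fix_h4 <- function() fixture("h4", function() {
  r <- 1.8 * sqd_constants()$bohr
  mol <- molecule(rep("H", 4), cbind(0, 0, (0:3) * r))
  bs <- build_basis(mol, "sto-3g")
  scf <- rhf(bs, conv = 1e-10)
  as_ <- active_space(4L, scf$C, scf$C[, integer(0), drop = FALSE])
  eri <- eri_integrals(bs)
  hmo <- build_active_hamiltonian(scf, as_, eri = eri)
  list(mol = mol, bs = bs, scf = scf, active = as_, hmo = hmo, eri = eri)
})

# H6 chain, STO-3G, (6e,6o): the solvated toy ladder
fix_h6 <- function() fixture("h6", function() {
  cfg <- run_config("h6", basis = "sto-3g",
                    active = list(frozen = 0L, n_orbitals = 6L),
                    shots = 5e4, p_flip = 0.02, seed = 7L,
                    batch_size = 60L, n_batches = 10L)
  chem <- sqdpcm:::.chem_stage(cfg)
  c(chem, list(config = cfg))
})

# water in STO-3G with a (6e,5o) window: the solvated mini system
fix_h2o_mini <- function() fixture("h2o_mini", function() {
  cfg <- run_config("h2o-mini", basis = "sto-3g",
                    active = list(frozen = 2L, n_orbitals = 5L),
                    shots = 2e4, p_flip = 0.02, seed = 7L,
                    batch_size = 10L, n_batches = 5L)
  chem <- sqdpcm:::.chem_stage(cfg)
  c(chem, list(config = cfg))
})

# a full-coverage noiseless sample set over a sector
full_coverage_samples <- function(norb, n_alpha) {
  st <- full_sector(norb, n_alpha)$U
  sample_set(rep(st, each = length(st)), rep(st, times = length(st)),
             rep(1, length(st)^2), norb)
}
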