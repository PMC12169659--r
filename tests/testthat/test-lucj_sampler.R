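# LUCJ state preparation, sector simulation, sampling and the noise emulator.

random_ccsd_amplitudes <- function(no, nv, sd = 0.05, seed = 42) {
  set.seed(seed)
  t1 <- matrix(rnorm(no * nv, sd = sd), no, nv)
  t2 <- array(rnorm(no^2 * nv^2, sd = sd), c(no, no, nv, nv))
  t2 <- (t2 + aperm(t2, c(2, 1, 4, 3))) / 2
  structure(list(t1 = t1, t2 = t2, n_occ = no, n_vir = nv, converged = TRUE),
            class = "ccsd_result")
}

test_that("LUCJ parameters have the required structure", {
  cc <- random_ccsd_amplitudes(2, 2)
  par <- derive_lucj_from_ccsd(cc, 4L)
  expect_lt(max(Mod(par$K1 + Conj(t(par$K1)))), 1e-12)   # anti-Hermitian
  expect_lt(max(abs(par$J_same - t(par$J_same))), 1e-12) # symmetric
  expect_lt(max(abs(par$K2 + t(par$K2))), 1e-12)
  # determinism: identical amplitudes give bitwise identical parameters
  par2 <- derive_lucj_from_ccsd(cc, 4L)
  expect_identical(par, par2)
  # t2 = 0: no Jastrow coupling, state reduces to a rotated determinant
  cc0 <- random_ccsd_amplitudes(2, 2)
  cc0$t2[] <- 0
  p0 <- derive_lucj_from_ccsd(cc0, 4L)
  expect_identical(max(abs(p0$J_same)), 0)
  st0 <- simulate_lucj_state(p0, 2L)
  # a rotated single determinant has rank-1 amplitude matrix
  sv <- svd(st0$amp)$d
  expect_lt(sv[2], 1e-10)
  expect_equal(sv[1], 1, tolerance = 1e-10)
})

test_that("identity circuit leaves the reference determinant", {
  cc <- random_ccsd_amplitudes(2, 2)
  cc$t1[] <- 0; cc$t2[] <- 0
  st <- simulate_lucj_state(derive_lucj_from_ccsd(cc, 4L), 2L)
  i0 <- match(3L, st$strings)
  expect_equal(Mod(st$amp[i0, i0]), 1, tolerance = 1e-12)
  expect_lt(sum(Mod(st$amp)^2) - Mod(st$amp[i0, i0])^2, 1e-20)
})

test_that("sector simulation matches the dense operator-exponential oracle", {
  cc <- random_ccsd_amplitudes(2, 2, sd = 0.08, seed = 3)
  par <- derive_lucj_from_ccsd(cc, 4L)
  st <- simulate_lucj_state(par, 2L)
  expect_equal(sum(Mod(st$amp)^2), 1, tolerance = 1e-10)
  strings <- st$strings
  N <- length(strings)
  i0 <- match(3L, strings)
  v <- rep(0 + 0i, N * N); v[(i0 - 1) * N + i0] <- 1
  v <- oracle_expm(oracle_sector_onebody(-par$K1, strings, 4L)) %*% v
  occ <- sqdpcm:::.occ_matrix(strings, 4L)
  qs <- 0.5 * rowSums((occ %*% par$J_same) * occ)
  Cx <- occ %*% par$J_cross %*% t(occ)
  ph <- outer(qs, rep(1, N)) + outer(rep(1, N), qs) + Cx
  v <- v * exp(1i * as.vector(ph))
  v <- oracle_expm(oracle_sector_onebody(par$K1, strings, 4L)) %*% v
  v <- oracle_expm(oracle_sector_onebody(-(par$K2 + 0i), strings, 4L)) %*% v
  expect_lt(max(Mod(as.vector(st$amp) - as.vector(v))), 1e-8)
})

test_that("the LUCJ state of H2 overlaps the FCI ground state", {
  mol <- builtin_molecule("h2")
  bs <- build_basis(mol, "sto-3g")
  scf <- rhf(bs, conv = 1e-11)
  as_ <- active_space(2L, scf$C, scf$C[, integer(0), drop = FALSE])
  hmo <- build_active_hamiltonian(scf, as_)
  cc <- ccsd(hmo)
  st <- simulate_lucj_state(derive_lucj_from_ccsd(cc, 2L), 1L)
  fci <- ci_ground_state(project_hamiltonian(hmo, full_sector(2L, 1L)))
  fid <- Mod(sum(Conj(st$amp) * fci$vector))^2
  expect_gt(fid, 0.99)
})

test_that("sampling is multinomial, reproducible and symmetry-preserving", {
  cc <- random_ccsd_amplitudes(2, 2, sd = 0.3, seed = 8)
  st <- simulate_lucj_state(derive_lucj_from_ccsd(cc, 4L), 2L)
  s1 <- sample_bitstrings(st, 1e5, seed = 13)
  s2 <- sample_bitstrings(st, 1e5, seed = 13)
  expect_identical(s1$records, s2$records)
  expect_equal(s1$shots, 1e5)
  # noiseless samples always carry exact particle number and spin-z
  expect_true(all(sqdpcm:::.popcount(s1$records$alpha, 4L) == 2L))
  expect_true(all(sqdpcm:::.popcount(s1$records$beta, 4L) == 2L))
  # empirical frequencies within 3 multinomial standard errors
  p <- Mod(st$amp)^2
  N <- length(st$strings)
  for (k in order(-p)[1:4]) {
    ib <- (k - 1) %% N + 1; ia <- (k - 1) %/% N + 1
    rec <- s1$records
    hit <- rec$alpha == st$strings[ia] & rec$beta == st$strings[ib]
    obs <- if (any(hit)) rec$count[hit] else 0
    se <- sqrt(1e5 * p[k] * (1 - p[k]))
    expect_lt(abs(obs - 1e5 * p[k]), 3 * se + 1)
  }
  # a state concentrated on one determinant yields a single bitstring
  cc0 <- random_ccsd_amplitudes(2, 2); cc0$t1[] <- 0; cc0$t2[] <- 0
  st0 <- simulate_lucj_state(derive_lucj_from_ccsd(cc0, 4L), 2L)
  s0 <- sample_bitstrings(st0, 500, seed = 2)
  expect_equal(nrow(s0$records), 1L)
  expect_equal(s0$records$count, 500)
  expect_error(sample_bitstrings(st0, 0), "positive")
})

test_that("bit-flip noise has the predicted statistics", {
  cc <- random_ccsd_amplitudes(3, 3, sd = 0.1, seed = 5)
  st <- simulate_lucj_state(derive_lucj_from_ccsd(cc, 6L), 3L)
  s <- sample_bitstrings(st, 2e4, seed = 4)
  # p = 0 is the identity
  expect_identical(inject_noise(s, 0, seed = 1), s)
  # fraction of symmetry-broken shots ~ 1 - (1-p)^(2 norb)
  p <- 0.01
  ns <- inject_noise(s, p, seed = 6)
  expect_equal(ns$shots, s$shots)
  broken <- sum(ns$records$count[
    sqdpcm:::.popcount(ns$records$alpha, 6L) != 3L |
    sqdpcm:::.popcount(ns$records$beta, 6L) != 3L])
  pb <- 1 - (1 - p)^12
  se <- sqrt(s$shots * pb * (1 - pb))
  expect_lt(abs(broken - s$shots * pb), 3 * se)
  # p = 0.5 uniformizes the per-bit marginals
  nu <- inject_noise(s, 0.5, seed = 7)
  occm <- sqdpcm:::.occ_matrix(nu$records$alpha, 6L)
  marg <- as.vector(crossprod(occm, nu$records$count)) / nu$shots
  se_m <- sqrt(0.25 / nu$shots)
  expect_true(all(abs(marg - 0.5) < 4 * se_m))
})

test_that("sample files round-trip and tolerate missing counts", {
  cc <- random_ccsd_amplitudes(2, 2, sd = 0.2, seed = 9)
  st <- simulate_lucj_state(derive_lucj_from_ccsd(cc, 4L), 2L)
  s <- inject_noise(sample_bitstrings(st, 5e3, seed = 3), 0.02, seed = 4)
  p <- tempfile(fileext = ".txt")
  write_sample_file(s, p)
  rd <- read_sample_file(p)
  key <- function(x) {
    r <- x$records[order(x$records$alpha, x$records$beta), ]
    rownames(r) <- NULL
    r
  }
  expect_equal(key(rd), key(s))
  expect_equal(rd$shots, s$shots)
  # missing counts default to 1
  writeLines(c("# norb=2", "1001", "0110 3"), p)
  rd2 <- read_sample_file(p)
  expect_equal(rd2$shots, 4)
  expect_equal(sort(rd2$records$count), c(1, 3))
})
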