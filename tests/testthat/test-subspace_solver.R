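# Projected Hamiltonians and the solvated SCRF ground-state solver.

test_that("projection keeps exact full-space matrix elements", {
  fx <- fix_h4()
  sec <- full_sector(4L, 2L)
  # full sector: lowest eigenvalue equals CASCI
  e_full <- ci_ground_state(project_hamiltonian(fx$hmo, sec))$energy
  Hd <- oracle_dense_h(fx$hmo$h1, fx$hmo$h2, sec$U, 4L)
  expect_equal(e_full, min(eigen(Hd, symmetric = TRUE)$values) + fx$hmo$e_core,
               tolerance = 1e-10)
  # single-determinant subspace: the diagonal matrix element
  rhf_str <- 3L
  sub1 <- configuration_subspace(rhf_str, 4L, 2L)
  e1 <- ci_ground_state(project_hamiltonian(fx$hmo, sub1))$energy
  Hd1 <- oracle_dense_h(fx$hmo$h1, fx$hmo$h2, rhf_str, 4L)
  expect_equal(e1, Hd1[1, 1] + fx$hmo$e_core, tolerance = 1e-10)
  expect_equal(e1, fx$scf$energy, tolerance = 1e-9)  # RHF determinant energy
  # random subspaces: action matches the dense brute force to 1e-10
  set.seed(5)
  for (rep in 1:3) {
    U <- sort(sample(sec$U, 4))
    sub <- configuration_subspace(U, 4L, 2L)
    prob <- project_hamiltonian(fx$hmo, sub)
    Hd <- oracle_dense_h(fx$hmo$h1, fx$hmo$h2, sub$U, 4L)
    x <- matrix(rnorm(16), 4, 4)
    expect_lt(max(abs(ci_matvec(prob, x) -
                      matrix(Hd %*% as.vector(x), 4, 4))), 1e-10)
  }
  expect_error(project_hamiltonian(fx$hmo,
    structure(list(U = integer(0), norb = 4L, n_alpha = 2L, d = 0),
              class = "config_subspace")), "empty")
})

test_that("matvec action is symmetric on random vectors", {
  fx <- fix_h4()
  prob <- project_hamiltonian(fx$hmo, full_sector(4L, 2L))
  set.seed(2)
  for (rep in 1:4) {
    u <- matrix(rnorm(36), 6, 6); v <- matrix(rnorm(36), 6, 6)
    expect_equal(sum(u * ci_matvec(prob, v)), sum(v * ci_matvec(prob, u)),
                 tolerance = 1e-10)
  }
})

test_that("a solvent operator folded into h1 shifts the spectrum exactly", {
  # one-electron perturbations enter through the same Slater-Condon path
  fx <- fix_h4()
  set.seed(8)
  V <- matrix(rnorm(16, sd = 0.05), 4, 4); V <- (V + t(V)) / 2
  sub <- full_sector(4L, 2L)
  e_pert <- ci_ground_state(project_hamiltonian(fx$hmo, sub, v_int = V))$energy
  Hd <- oracle_dense_h(fx$hmo$h1 + V, fx$hmo$h2, sub$U, 4L)
  expect_equal(e_pert, min(eigen(Hd, symmetric = TRUE)$values) + fx$hmo$e_core,
               tolerance = 1e-10)
})

test_that("epsilon = 1 follows the gas-phase path bit-for-bit", {
  fx <- fix_h2o_mini()
  sub <- full_sector(5L, 3L)
  gas <- solve_scrf_ground_state(fx$hmo, sub, pcm = NULL)
  eps1 <- solve_scrf_ground_state(fx$hmo, sub, pcm = pcm_config(epsilon = 1))
  expect_identical(eps1$E, gas$E)
  expect_identical(eps1$psi, gas$psi)
  expect_identical(eps1$e_pol, 0)
})

test_that("SCRF lowers the free energy and converges the charges", {
  fx <- fix_h2o_mini()
  sub <- full_sector(5L, 3L)
  res <- solve_scrf_ground_state(fx$hmo, sub, pcm = fx$pcm_state)
  expect_true(res$converged)
  expect_lt(res$E, res$E_gas)          # polar solute is stabilized
  expect_lt(res$e_pol, 0)
  n <- nrow(res$scrf_log)
  expect_lt(res$scrf_log$dq[n], 1e-6)
  # stationarity: the converged free energy is (locally) minimal among
  # normalized perturbed CI vectors evaluated through the free-energy
  # functional G(psi) = <psi|H0|psi> + 1/2 q(psi) . phi(psi)
  prob <- project_hamiltonian(fx$hmo, sub)
  Gfun <- function(psi) {
    psi <- psi / sqrt(sum(psi^2))
    g <- ci_rdm1(prob, psi)
    Dc <- if (ncol(fx$hmo$C_core)) 2 * tcrossprod(fx$hmo$C_core) else 0
    D <- Dc + fx$hmo$C_act %*% g$total %*% t(fx$hmo$C_act)
    fld <- pcm_field(fx$pcm_state, D)
    sum(psi * ci_matvec(prob, psi)) + fx$hmo$e_core + fld$e_pol
  }
  G0 <- Gfun(res$psi)
  expect_equal(G0, res$E, tolerance = 1e-6)
  set.seed(4)
  for (rep in 1:3) {
    pert <- res$psi + matrix(rnorm(length(res$psi), sd = 2e-3),
                             nrow(res$psi), ncol(res$psi))
    expect_gt(Gfun(pert), G0 - 1e-12)
  }
})

test_that("gas-phase subspace energies nest variationally", {
  fx <- fix_h4()
  sec <- full_sector(4L, 2L)
  # a nested chain S1 subset S2 subset full sector
  U_sorted <- sec$U[order(apply(ci_hdiag(project_hamiltonian(fx$hmo, sec)), 2, min))]
  chain <- list(U_sorted[1:2], U_sorted[1:4], sec$U)
  es <- vapply(chain, function(U)
    ci_ground_state(project_hamiltonian(fx$hmo,
      configuration_subspace(U, 4L, 2L)))$energy, 0)
  expect_true(all(diff(es) <= 1e-12))
})

test_that("batch selection takes the minimum with deterministic ties", {
  r1 <- structure(list(E = -115.10), class = "solvated_result")
  r2 <- structure(list(E = -115.12), class = "solvated_result")
  r3 <- structure(list(E = -115.12), class = "solvated_result")
  expect_identical(select_best_batch(list(r1))$batch, 1L)
  expect_identical(select_best_batch(list(r1, r2))$batch, 2L)
  expect_identical(select_best_batch(list(r1, r2, r3))$batch, 2L) # tie -> first
  expect_error(select_best_batch(list()), "no batch")
})

test_that("solvation free energies have the right limits", {
  fx <- fix_h2o_mini()
  sub <- full_sector(5L, 3L)
  gas <- solve_scrf_ground_state(fx$hmo, sub, pcm = NULL)
  expect_error(gsolv(list(E = 1)), "solvated_result")
  gv0 <- gsolv(gas)
  expect_identical(gv0$gsolv, 0)       # eps = 1 / gas: zero by construction
  sol <- solve_scrf_ground_state(fx$hmo, sub, pcm = fx$pcm_state)
  gv <- gsolv(sol)
  expect_lt(gv$gsolv, 0)
  expect_equal(gv$delta_hartree * sqd_constants()$hartree_kcal, gv$gsolv)
  # Born-ion route through the same conversion: analytic within 0.5%
  eps <- 78.3553; a <- 2
  cfg <- pcm_config(points_per_sphere = 590, radii_scale = 1)
  cav <- build_cavity(molecule("H", matrix(0, 1, 3)), cfg,
                      radii = a * sqd_constants()$bohr)
  ch <- solve_surface_charge(assemble_operators(cav, eps),
                             1 / sqrt(rowSums(cav$points^2)))
  born_kcal <- polarization_energy(ch) * sqd_constants()$hartree_kcal
  ref <- -0.5 * (1 - 1 / eps) / a * sqd_constants()$hartree_kcal
  expect_lt(abs(born_kcal - ref) / abs(ref), 0.005)
})
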