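# Molecular setup: geometries, basis/integral engine, AVAS selection,
# active-space Hamiltonians, Hilbert dimensions, FCIDUMP round trips.

test_that("molecule invariants and XYZ round trip", {
  expect_error(molecule("H", matrix(c(0, 0, NA), 1, 3)), "finite")
  expect_error(molecule(c("H", "H"), matrix(0, 1, 3)), "count")
  expect_error(molecule("H", matrix(0, 1, 3), charge = 1L), "closed-shell|neutral")
  mol <- builtin_molecule("methanol")
  expect_identical(mol$elements, c("C", "O", "H", "H", "H", "H"))
  p <- tempfile(fileext = ".xyz")
  write_xyz(mol, p, comment = "round trip")
  m2 <- read_xyz(p)
  expect_equal(m2$coords, mol$coords, tolerance = 1e-9)
})

test_that("RHF reproduces the literature water/cc-pVDZ energy", {
  mol <- molecule(c("O", "H", "H"),
                  matrix(c(0, 0, 0.1173, 0, 0.7572, -0.4692, 0, -0.7572, -0.4692),
                         3, 3, byrow = TRUE))
  bs <- build_basis(mol, "cc-pvdz")
  expect_equal(bs$nao, 24L)
  scf <- rhf(bs)
  # independently published RHF/cc-pVDZ value at the experimental geometry
  expect_equal(scf$energy, -76.02677, tolerance = 2e-4)
})

test_that("already-converged geometry is a fixed point of the optimizer", {
  mol <- builtin_molecule("h2")
  opt1 <- optimize_geometry(mol, basis = "sto-3g", grad_tol = 5e-4)
  opt2 <- optimize_geometry(opt1, basis = "sto-3g", grad_tol = 5e-4)
  expect_lt(max(abs(opt2$coords - opt1$coords)), 2e-3)
  expect_true(attr(opt2, "converged"))
})

test_that("H2 optimization agrees with a dense 1-D bond scan oracle", {
  mol <- molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 2.0), 2, 3, byrow = TRUE))
  opt <- optimize_geometry(mol, basis = "sto-3g")
  r_opt <- sqrt(sum((opt$coords[1, ] - opt$coords[2, ])^2))
  # oracle: quadratic fit through a fine energy scan
  rs <- seq(0.68, 0.76, by = 0.002)
  es <- vapply(rs, function(r) {
    m <- molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, r), 2, 3, byrow = TRUE))
    single_point(m, "sto-3g")$energy
  }, 0)
  k <- which.min(es)
  fit <- lm(es[(k - 3):(k + 3)] ~ poly(rs[(k - 3):(k + 3)], 2, raw = TRUE))
  r_star <- -coef(fit)[2] / (2 * coef(fit)[3])
  expect_lt(abs(r_opt - r_star), 1e-3)
})

test_that("AVAS reproduces the published active-space sizes", {
  # methanol: C[2s,2p], O[2s,2p], H[1s] -> (14e,12o)
  mol <- builtin_molecule("methanol")
  bs <- build_basis(mol, "cc-pvdz")
  scf <- rhf(bs)
  as_ <- select_active_space_avas(scf, c("C 2s", "C 2p", "O 2s", "O 2p", "H 1s"))
  expect_equal(as_$n_electrons, 14L)
  expect_equal(as_$n_orbitals, 12L)
  # orbital coefficients orthonormal under the AO overlap metric
  Sm <- crossprod(as_$C_act, scf$ints$S %*% as_$C_act)
  expect_lt(max(abs(Sm - diag(12))), 1e-10)
  # water: everything minus the oxygen-core MO -> (8e,23o)
  w <- builtin_molecule("water")
  bw <- build_basis(w, "cc-pvdz")
  sw <- rhf(bw)
  aw <- select_active_space_avas(sw, "!O 1s")
  expect_equal(aw$n_electrons, 8L)
  expect_equal(aw$n_orbitals, 23L)
  # a label list covering the whole basis selects everything
  all_labels <- unique(bw$ao_label)
  all_labels <- sub("^([A-Za-z]+)[0-9]+ ", "\\1 ", all_labels)
  aa <- select_active_space_avas(sw, unique(all_labels))
  expect_equal(aa$n_orbitals, bw$nao)
  expect_equal(aa$n_electrons, 10L)
  expect_error(select_active_space_avas(sw, character(0)), "no functions|specification")
})

test_that("Hilbert dimensions match the published table exactly", {
  dims <- list(c(14L, 12L, 627264), c(14L, 13L, 2944656),
               c(20L, 18L, 1914762564), c(8L, 23L, 78411025))
  for (d in dims)
    expect_identical(hilbert_dimension(list(n_electrons = d[1], n_orbitals = d[2])),
                     as.numeric(d[3]))
  expect_identical(hilbert_dimension(list(n_electrons = 2, n_orbitals = 2)), 4)
  expect_error(hilbert_dimension(list(n_electrons = 3, n_orbitals = 4)), "odd|unsupported")
})

test_that("active Hamiltonian integrals carry the required symmetries", {
  fx <- fix_h4()
  h2 <- fx$hmo$h2
  expect_lt(max(abs(fx$hmo$h1 - t(fx$hmo$h1))), 1e-12)
  for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2)))
    expect_lt(max(abs(h2 - aperm(h2, perm))), 1e-10)
})

test_that("full-space diagonalization of the active Hamiltonian equals FCI", {
  fx <- fix_h4()
  sol <- ci_ground_state(project_hamiltonian(fx$hmo, full_sector(4L, 2L)))
  Hd <- oracle_dense_h(fx$hmo$h1, fx$hmo$h2, full_sector(4L, 2L)$U, 4L)
  e_or <- min(eigen((Hd + t(Hd)) / 2, symmetric = TRUE)$values) + fx$hmo$e_core
  expect_equal(sol$energy, e_or, tolerance = 1e-10)
})

test_that("frozen-core energies match a core-restricted all-electron oracle", {
  # water/STO-3G with 2 frozen orbitals: compare against the all-electron
  # Hamiltonian diagonalized over determinants whose core bits stay occupied
  mol <- builtin_molecule("h2o-mini")
  bs <- build_basis(mol, "sto-3g")
  scf <- rhf(bs, conv = 1e-10)
  eri <- eri_integrals(bs)
  as_full <- active_space(10L, scf$C, scf$C[, integer(0), drop = FALSE])
  hmo_full <- build_active_hamiltonian(scf, as_full, eri = eri)
  as_frz <- active_space_window(scf, 2L, 5L)
  hmo_frz <- build_active_hamiltonian(scf, as_frz, eri = eri)
  e_frz <- ci_ground_state(project_hamiltonian(hmo_frz, full_sector(5L, 3L)))$energy
  # oracle: all-electron H over the 7-orbital space, restricted to strings
  # with orbitals 1,2 occupied
  U_all <- full_sector(7L, 5L)$U
  keep <- bitwAnd(U_all, 3L) == 3L
  U_res <- U_all[keep]
  Hd <- oracle_dense_h(hmo_full$h1, hmo_full$h2, U_res, 7L)
  e_or <- min(eigen((Hd + t(Hd)) / 2, symmetric = TRUE)$values) + hmo_full$e_core
  expect_equal(e_frz, e_or, tolerance = 1e-8)
})

test_that("FCIDUMP files round-trip and preserve the spectrum", {
  fx <- fix_h4()
  p <- tempfile(fileext = ".fcidump")
  write_fcidump(fx$hmo, p)
  rd <- read_fcidump(p)
  expect_equal(rd$n_electrons, 4L)
  expect_equal(rd$n_orbitals, 4L)
  expect_equal(rd$h1, fx$hmo$h1, tolerance = 1e-12)
  expect_equal(rd$h2, fx$hmo$h2, tolerance = 1e-12)
  e1 <- ci_ground_state(project_hamiltonian(fx$hmo, full_sector(4L, 2L)))$energy
  e2 <- ci_ground_state(project_hamiltonian(rd, full_sector(4L, 2L)))$energy
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("the packaged water structure is converged in solution", {
  opt <- optimize_geometry(builtin_molecule("water"), basis = "cc-pvdz",
                           pcm = pcm_config())
  expect_lt(attr(opt, "max_grad"), 3e-4)
  expect_true(attr(opt, "converged"))
})
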