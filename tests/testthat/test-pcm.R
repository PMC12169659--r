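# IEF-PCM boundary-element solver: cavity geometry, operator identities,
# surface-charge solutions against analytic electrostatics.

born_cavity <- function(points, a_bohr = 2) {
  cfg <- pcm_config(points_per_sphere = points, radii_scale = 1)
  build_cavity(molecule("H", matrix(0, 1, 3)), cfg,
               radii = a_bohr * sqd_constants()$bohr)
}

test_that("cavity geometry invariants hold", {
  # single atom: exposed area equals the full sphere area
  cav <- born_cavity(302)
  expect_equal(sum(cav$areas), 4 * pi * 2^2, tolerance = 1e-8)
  expect_lt(max(abs(sqrt(rowSums(cav$normals^2)) - 1)), 1e-12)
  # two overlapping spheres: occlusion reduces the area
  m2 <- molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 0.9), 2, 3, byrow = TRUE))
  cav2 <- build_cavity(m2, pcm_config(points_per_sphere = 302))
  r_b <- 1.2 * 1.2 / sqd_constants()$bohr
  expect_lt(sum(cav2$areas), 2 * 4 * pi * r_b^2)
  # every retained point lies outside every other scaled sphere
  w <- builtin_molecule("water")
  cw <- build_cavity(w, pcm_config(points_per_sphere = 110))
  for (A in seq_len(nrow(cw$centers))) {
    others <- cw$sphere != A
    d <- sqrt(rowSums(sweep(cw$points[others, , drop = FALSE], 2, cw$centers[A, ])^2))
    expect_true(all(d > cw$radii[A] - 1e-9))
  }
})

test_that("boundary operators satisfy kernel identities", {
  # two isolated points at distance 2 bohr: off-diagonal S = 1/r = 0.5
  cav <- born_cavity(302)
  p1 <- cav$points[1, ];
  ops <- assemble_operators(cav, 78.3553)
  i <- 1; j <- which.max(rowSums(sweep(cav$points, 2, p1)^2))
  rij <- sqrt(sum((cav$points[i, ] - cav$points[j, ])^2))
  expect_equal(ops$S[i, j], 1 / rij, tolerance = 1e-12)
  expect_identical(ops$S, t(ops$S))
  # Gauss solid-angle rule: off-diagonal row sums of D * areas near -2 pi
  cav590 <- born_cavity(590)
  ops590 <- assemble_operators(cav590, 2)
  D0 <- ops590$D; diag(D0) <- 0
  rs <- as.vector(D0 %*% cav590$areas)
  expect_true(all(abs(rs - (-2 * pi)) < 0.05 * 2 * pi))
  expect_error(assemble_operators(
    structure(list(points = matrix(0, 2, 3), areas = c(1, 1),
                   normals = matrix(c(0, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE)),
              class = "pcm_cavity"), 2), "coincident")
})

test_that("surface charges obey the dielectric limits", {
  cav <- born_cavity(590)
  phi <- 1 / sqrt(rowSums(cav$points^2)) # unit charge at the center
  # eps = 1: no response
  ops1 <- assemble_operators(cav, 1)
  ch1 <- solve_surface_charge(ops1, phi)
  expect_identical(ch1$q, numeric(nrow(cav$points)))
  # strong dielectric: total apparent charge -> -q (eps-1)/eps within 1%
  for (eps in c(78.3553, 1e6)) {
    ch <- solve_surface_charge(assemble_operators(cav, eps), phi)
    expect_lt(ch$residual, 1e-10)
    expect_equal(sum(ch$q), -(eps - 1) / eps, tolerance = 1e-2)
  }
})

test_that("Born ion polarization energy matches the analytic formula", {
  eps <- 78.3553; a <- 2
  ref <- -0.5 * (1 - 1 / eps) / a
  errs <- vapply(c(110, 302, 590), function(np) {
    cav <- born_cavity(np, a)
    phi <- 1 / sqrt(rowSums(cav$points^2))
    ch <- solve_surface_charge(assemble_operators(cav, eps), phi)
    abs(polarization_energy(ch) - ref) / abs(ref)
  }, 0)
  expect_lt(errs[3], 0.005)
  expect_true(all(diff(errs) < 0))   # monotone refinement
})

test_that("the solvent operator folds charges back consistently", {
  fx <- fix_h2o_mini()
  state <- fx$pcm_state
  D <- fx$scf$D
  fld <- pcm_field(state, D)
  sop <- solvent_operator(structure(list(q = fld$q, sigma = fld$q / state$cavity$areas,
                                         phi = fld$phi), class = "surface_charge"),
                          fx$bs, state$cavity)
  expect_lt(max(abs(sop$V - t(sop$V))), 1e-12)
  expect_equal(sop$V, fld$V, tolerance = 1e-10)
  # contraction with the generating density reproduces the electron part of
  # sum_k q_k phi(s_k)
  phi_el <- -as.vector(crossprod(state$Tm, as.vector(D)))
  expect_equal(sum(D * sop$V), sum(fld$q * phi_el), tolerance = 1e-8)
  # zero charges -> zero operator
  z <- structure(list(q = numeric(nrow(state$cavity$points))), class = "surface_charge")
  sz <- solvent_operator(z, fx$bs, state$cavity)
  expect_identical(max(abs(sz$V)), 0)
  expect_identical(sz$e_nuc_int, 0)
})

test_that("potential integrals match the analytic Gaussian formula", {
  # contracted s function: (i|1/|r-C||j) = sum_ij c_i c_j (2 pi / p) F0(p R^2)
  mol <- molecule("H", matrix(0, 1, 3))
  bs <- build_basis(mol, "sto-3g")
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  for (R in c(1.5, 4, 20)) {
    v <- esp_integrals(bs, matrix(c(0, 0, R), 1, 3))[1, 1, 1]
    cs <- bs$shells[[1]]$coefs * bs$norm[1]
    ex <- bs$shells[[1]]$exps
    ref <- 0
    for (i in seq_along(ex)) for (j in seq_along(ex)) {
      p <- ex[i] + ex[j]
      T_ <- p * R^2
      ref <- ref + cs[i] * cs[j] * (2 * pi / p) * 0.5 * sqrt(pi / T_) * erf(sqrt(T_))
    }
    expect_equal(v, ref, tolerance = 1e-12)
  }
})

test_that("solvated SCF stabilizes neutral polar solutes", {
  fx <- fix_h2o_mini()
  scf_gas <- rhf(fx$bs, ints = fx$ints, eri = fx$eri)
  expect_lt(fx$scf$e_pol, 0)
  expect_lt(fx$scf$energy, scf_gas$energy)
})

test_that("operator symmetry holds for a symmetric molecule", {
  # water (C2v, mirror y -> -y swaps the hydrogens): the reaction-field
  # operator of the symmetric SCF density must commute with the mirror's
  # AO representation (atom swap + sign flip on y-odd components)
  fx <- fix_h2o_mini()
  bs <- fx$bs
  n <- bs$nao
  Tm <- matrix(0, n, n)
  off <- 0L
  # destination offset per shell after swapping atoms 2 and 3
  shell_sizes <- vapply(bs$shells, function(s) c(1L, 3L, 5L)[s$l + 1L], 0L)
  shell_off <- cumsum(c(0L, head(shell_sizes, -1L)))
  atom_map <- c(1L, 3L, 2L)
  for (k in seq_along(bs$shells)) {
    l <- bs$shells[[k]]$l
    at <- bs$shell_atom[k]
    # matching shell on the mapped atom: same position within that atom
    k2 <- which(bs$shell_atom == atom_map[at])[which(which(bs$shell_atom == at) == k)]
    sgn <- switch(l + 1L, 1, c(1, -1, 1), c(-1, -1, 1, 1, 1)) # y -> -y
    for (c_ in seq_len(shell_sizes[k]))
      Tm[shell_off[k2] + c_, shell_off[k] + c_] <- sgn[c_]
    off <- off + shell_sizes[k]
  }
  fld <- pcm_field(fx$pcm_state, fx$scf$D)
  V <- fld$V
  # the spiral surface grid is not itself mirror-symmetric, so the commutator
  # vanishes only to quadrature resolution (refines with points_per_sphere)
  expect_lt(max(abs(Tm %*% V %*% t(Tm) - V)), 1e-4)
})
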