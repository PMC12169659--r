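# S-CORE configuration recovery, batching and occupancy updates.

test_that("initial occupancy averages only the symmetry-correct shots", {
  # all shots equal to the RHF determinant: occupancy equals its pattern
  rhf <- sum(bitwShiftL(1L, 0:2))                 # orbitals 0..2 of 6
  s <- sample_set(rhf, rhf, 100, 6L)
  oc <- initial_occupancy(s, 3L, 3L)
  expect_identical(oc$alpha, c(1, 1, 1, 0, 0, 0))
  # two correct strings with counts 3:1: weighted mean
  s2 <- sample_set(c(7L, 56L), c(7L, 7L), c(3, 1), 6L)
  oc2 <- initial_occupancy(s2, 3L, 3L)
  expect_equal(oc2$alpha, c(0.75, 0.75, 0.75, 0.25, 0.25, 0.25))
  expect_identical(oc2$beta, c(1, 1, 1, 0, 0, 0))
  # a broken-only set fails loudly
  s3 <- sample_set(3L, 7L, 10, 6L)                # alpha has 2 electrons
  expect_error(initial_occupancy(s3, 3L, 3L), "no symmetry-correct")
})

test_that("recovery restores exact particle numbers and passes through", {
  set.seed(1)
  norb <- 12L; na <- 7L
  # corrupted shots around a random reference configuration
  base <- sum(bitwShiftL(1L, 0:6))
  oc <- occupancy(c(rep(0.95, 7), rep(0.05, 5)), c(rep(0.95, 7), rep(0.05, 5)))
  a <- integer(100); b <- integer(100)
  for (i in 1:100) {
    flip <- sample(0:11, sample(0:3, 1))
    a[i] <- Reduce(bitwXor, c(base, bitwShiftL(1L, flip)))
    flip <- sample(0:11, sample(0:3, 1))
    b[i] <- Reduce(bitwXor, c(base, bitwShiftL(1L, flip)))
  }
  s <- sample_set(a, b, rep(1, 100), norb)
  rec <- recover_configurations(s, oc, na, na, seed = 5)
  expect_equal(rec$shots, s$shots)
  expect_true(all(sqdpcm:::.popcount(rec$records$alpha, norb) == na))
  expect_true(all(sqdpcm:::.popcount(rec$records$beta, norb) == na))
  # idempotence on symmetry-correct sets: strings pass through unchanged
  rec2 <- recover_configurations(rec, oc, na, na, seed = 9)
  expect_equal(rec2$records, rec$records)
})

test_that("flip choice follows the occupancy-distance weighting", {
  # one surplus alpha electron; occupancy sharply identifies orbital 3 (the
  # largest |x - n|): it must be flipped most often over seeded trials
  norb <- 4L
  mask <- as.integer(1 + 2 + 8)     # orbitals 0, 1, 3 occupied; target 2
  oc <- occupancy(c(0.95, 0.75, 0.2, 0.1), c(0.5, 0.5, 0.5, 0.5))
  hits <- integer(norb)
  for (seed in 1:2000) {
    s <- sample_set(mask, 3L, 1, norb)
    r <- recover_configurations(s, oc, 2L, 2L, seed = seed)
    gone <- bitwAnd(mask, bitwNot(r$records$alpha))
    hits <- hits + bitwAnd(bitwShiftR(gone, 0:3), 1L)
  }
  # weights for occupied bits are 1 - n: (0.05, 0.25, -, 0.90)
  expect_equal(which.max(hits), 4L)
  probs <- c(0.05, 0.25, 0.90) / 1.2
  expect_equal(hits[c(1, 2, 4)] / 2000, probs, tolerance = 0.06)
  expect_identical(hits[3], 0L)     # virtual orbital never flipped on surplus
})

test_that("batches are drawn reproducibly and without replacement", {
  set.seed(3)
  strings <- full_sector(6L, 3L)$U
  idx <- sample(length(strings), 15)
  s <- sample_set(strings[idx], rev(strings[idx]), sample(1:50, 15), 6L)
  b1 <- partition_batches(s, K = 4, batch_size = 6, seed = 11)
  b2 <- partition_batches(s, K = 4, batch_size = 6, seed = 11)
  expect_identical(b1, b2)
  expect_length(b1, 4)
  for (b in b1) expect_equal(anyDuplicated(paste(b$alpha, b$beta)), 0L)
  # batch_size = all distinct strings: every batch is the full set
  ball <- partition_batches(s, K = 3, batch_size = 15, seed = 2)
  for (b in ball) expect_equal(nrow(b), 15L)
  expect_warning(partition_batches(s, K = 1, batch_size = 99, seed = 1), "truncat")
})

test_that("spin-inversion closure yields d = |U|^2 and contains mirrors", {
  b <- data.frame(alpha = 7L, beta = 11L)        # a != b
  sub <- close_under_spin_inversion(b, 4L, 3L)
  expect_equal(length(sub$U), 2L)
  expect_equal(sub$d, 4)
  expect_true(all(c(7L, 11L) %in% sub$U))
  # spin-symmetric batch: d = (#distinct strings)^2
  bs_ <- data.frame(alpha = c(7L, 11L, 13L), beta = c(7L, 11L, 13L))
  expect_equal(close_under_spin_inversion(bs_, 4L, 3L)$d, 9)
  # randomized batches: d >= batch size always
  set.seed(9)
  strings <- full_sector(6L, 3L)$U
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    bb <- data.frame(alpha = sample(strings, n), beta = sample(strings, n))
    sub <- close_under_spin_inversion(bb, 6L, 3L)
    expect_gte(sub$d, n)
    expect_equal(sub$d, length(sub$U)^2)
  }
})

test_that("occupancy updates average the batch diagonal densities", {
  fx <- fix_h4()
  sub <- full_sector(4L, 2L)
  prob <- project_hamiltonian(fx$hmo, sub)
  # K = 1 with a single determinant: occupancies equal its bits
  v <- matrix(0, 6, 6); i0 <- match(3L, sub$U); v[i0, i0] <- 1
  r1 <- list(occupancies = list(alpha = diag(sqdpcm:::cpp_rdm1_side(prob$tab, v)),
                                beta = diag(sqdpcm:::cpp_rdm1_side(prob$tab, t(v)))))
  oc1 <- update_occupancy(list(r1))
  expect_identical(oc1$alpha, c(1, 1, 0, 0))
  # two batches with known densities: arithmetic mean
  r2 <- list(occupancies = list(alpha = c(0, 1, 1, 0), beta = c(0, 0, 1, 1)))
  ocm <- update_occupancy(list(r1, r2))
  expect_equal(ocm$alpha, c(0.5, 1, 0.5, 0))
  expect_equal(ocm$beta, c(0.5, 0.5, 0.5, 0.5))
  # random multi-determinant vector against the dense diagonal oracle
  set.seed(21)
  C <- matrix(rnorm(36), 6, 6); C <- C / sqrt(sum(C^2))
  g <- ci_rdm1(prob, C)
  occm <- sqdpcm:::.occ_matrix(sub$U, 4L)
  # oracle: n_p(alpha) = sum over determinants |c|^2 occ_p(alpha string)
  w_a <- colSums(C^2)            # weight per alpha string (columns)
  w_b <- rowSums(C^2)
  expect_equal(diag(g$alpha), as.vector(crossprod(occm, w_a)), tolerance = 1e-12)
  expect_equal(diag(g$beta), as.vector(crossprod(occm, w_b)), tolerance = 1e-12)
  # sums conserve the per-spin electron counts
  expect_equal(sum(diag(g$alpha)), 2, tolerance = 1e-12)
})
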