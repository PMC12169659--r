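# R-side drivers for the McMurchie-Davidson integral engine: assemble
# spherical, normalized AO matrices/tensors from the raw cartesian output.

.to_sph2 <- function(M, bs) {
  out <- crossprod(bs$Ct, M %*% bs$Ct)
  out * tcrossprod(bs$norm)
}

#' One-electron integrals
#'
#' Overlap, kinetic and nuclear-attraction matrices over the spherical,
#' normalized AO basis (Hartree atomic units).
#'
#' @param bs a `basis_set` from [build_basis()].
#' @return List with matrices `S`, `T`, `V` and the core Hamiltonian `H` =
#'   `T + V`, plus the nuclear repulsion energy `e_nuc`.
#' @export
one_electron_integrals <- function(bs) {
  xyz <- bs$mol$coords / .const$bohr
  Z <- element_Z(bs$mol$elements)
  raw <- cpp_one_electron(bs$shells, xyz, as.numeric(Z))
  S <- .to_sph2(raw$S, bs); T <- .to_sph2(raw$T, bs); V <- .to_sph2(raw$V, bs)
  e_nuc <- 0
  n <- nrow(xyz)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      e_nuc <- e_nuc + Z[i] * Z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  list(S = S, T = T, V = V, H = T + V, e_nuc = e_nuc)
}

#' Two-electron repulsion integrals
#'
#' Full (11|22)-convention ERI tensor over spherical normalized AOs.
#'
#' @param bs a `basis_set`.
#' @param screen_tol Cauchy-Schwarz screening threshold on shell pairs.
#' @return 4-dimensional array `(nao, nao, nao, nao)` in Hartree.
#' @export
eri_integrals <- function(bs, screen_tol = 1e-12) {
  arr <- cpp_eri(bs$shells, screen_tol)
  nc <- bs$ncart; ns <- bs$nao
  Ctn <- bs$Ct * rep(1, nc)  # (ncart x nsph)
  for (k in 1:4) {
    d <- dim(arr)
    m <- crossprod(Ctn, matrix(arr, d[1], prod(d[2:4])))
    m <- m * bs$norm
    arr <- array(m, c(ns, d[2], d[3], d[4]))
    arr <- aperm(arr, c(2, 3, 4, 1))
  }
  arr
}

#' Electrostatic-potential integrals at points
#'
#' Matrices (mu | 1/|r-s_k| | nu) for each point `s_k`, over spherical
#' normalized AOs.
#'
#' @param bs a `basis_set`.
#' @param points_bohr numeric matrix (k x 3), Bohr.
#' @return Array `(nao, nao, k)`.
#' @export
esp_integrals <- function(bs, points_bohr) {
  if (!is.matrix(points_bohr)) points_bohr <- matrix(points_bohr, ncol = 3)
  arr <- cpp_esp_tensor(bs$shells, points_bohr)
  d <- dim(arr); ns <- bs$nao
  for (k in 1:2) {
    d <- dim(arr)
    m <- crossprod(bs$Ct, matrix(arr, d[1], prod(d[2:3])))
    m <- m * bs$norm
    arr <- array(m, c(ns, d[2], d[3]))
    arr <- aperm(arr, c(2, 3, 1))
  }
  aperm(arr, c(2, 3, 1))
}
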