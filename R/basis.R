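# Gaussian basis-set data and shell construction.
#
# Parameters are the standard published cc-pVDZ (Dunning) and STO-3G sets for
# H, C, N, O, transcribed to full printed precision.  Contraction coefficients
# refer to normalized primitives; the axial primitive norms are folded in when
# shells are built, and each contracted spherical AO is renormalized to unit
# self-overlap afterwards.

.basis_data <- list(
  "cc-pvdz" = list(
    H = list(
      list(l = 0L, exps = c(13.0100, 1.9620, 0.4446), coefs = c(0.0196850, 0.1379770, 0.4781480)),
      list(l = 0L, exps = 0.1220, coefs = 1.0),
      list(l = 1L, exps = 0.7270, coefs = 1.0)
    ),
    C = list(
      list(l = 0L,
           exps = c(6665.0, 1000.0, 228.0, 64.71, 21.06, 6.459, 2.066, 0.5829, 0.1834),
           coefs = c(0.0006920, 0.0053290, 0.0270770, 0.1017180, 0.2747400,
                     0.4485640, 0.2850740, 0.0152040, -0.0031910)),
      list(l = 0L,
           exps = c(6665.0, 1000.0, 228.0, 64.71, 21.06, 6.459, 2.066, 0.5829, 0.1834),
           coefs = c(-0.0001460, -0.0011540, -0.0057250, -0.0233120, -0.0639550,
                     -0.1499810, -0.1272620, 0.5445290, 0.5804960)),
      list(l = 0L, exps = 0.1834, coefs = 1.0),
      list(l = 1L, exps = c(9.4390, 2.0020, 0.5456, 0.1517),
           coefs = c(0.0381090, 0.2094800, 0.5085570, 0.4688420)),
      list(l = 1L, exps = 0.1517, coefs = 1.0),
      list(l = 2L, exps = 0.5500, coefs = 1.0)
    ),
    N = list(
      list(l = 0L,
           exps = c(9046.0, 1357.0, 309.3, 87.73, 28.56, 9.464, 3.010, 0.7011, 0.2126),
           coefs = c(0.0007000, 0.0053890, 0.0274060, 0.1032070, 0.2787230,
                     0.4485400, 0.2782380, 0.0154400, -0.0028640)),
      list(l = 0L,
           exps = c(9046.0, 1357.0, 309.3, 87.73, 28.56, 9.464, 3.010, 0.7011, 0.2126),
           coefs = c(-0.0001530, -0.0012080, -0.0059920, -0.0245440, -0.0674590,
                     -0.1580780, -0.1218310, 0.5490030, 0.5788150)),
      list(l = 0L, exps = 0.2126, coefs = 1.0),
      list(l = 1L, exps = c(13.5500, 2.9170, 0.7973, 0.2185),
           coefs = c(0.0399190, 0.2171690, 0.5103190, 0.4622060)),
      list(l = 1L, exps = 0.2185, coefs = 1.0),
      list(l = 2L, exps = 0.8170, coefs = 1.0)
    ),
    O = list(
      list(l = 0L,
           exps = c(11720.0, 1759.0, 400.8, 113.7, 37.03, 13.27, 5.025, 1.013, 0.3023),
           coefs = c(0.0007100, 0.0054700, 0.0278370, 0.1048000, 0.2830620,
                     0.4487190, 0.2709520, 0.0154580, -0.0025850)),
      list(l = 0L,
           exps = c(11720.0, 1759.0, 400.8, 113.7, 37.03, 13.27, 5.025, 1.013, 0.3023),
           coefs = c(-0.0001600, -0.0012630, -0.0062670, -0.0257160, -0.0709240,
                     -0.1654110, -0.1169550, 0.5573680, 0.5727590)),
      list(l = 0L, exps = 0.3023, coefs = 1.0),
      list(l = 1L, exps = c(17.7000, 3.8540, 1.0460, 0.2753),
           coefs = c(0.0430180, 0.2289130, 0.5087280, 0.4605310)),
      list(l = 1L, exps = 0.2753, coefs = 1.0),
      list(l = 2L, exps = 1.1850, coefs = 1.0)
    )
  ),
  "sto-3g" = list(
    H = list(
      list(l = 0L, exps = c(3.425250914, 0.6239137298, 0.1688554040),
           coefs = c(0.1543289673, 0.5353281423, 0.4446345422))
    ),
    C = list(
      list(l = 0L, exps = c(71.6168370, 13.0450960, 3.5305122),
           coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
      list(l = 0L, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = c(-0.09996723, 0.39951283, 0.70115470)),
      list(l = 1L, exps = c(2.9412494, 0.6834831, 0.2222899),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    ),
    N = list(
      list(l = 0L, exps = c(99.1061690, 18.0523120, 4.8856602),
           coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
      list(l = 0L, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = c(-0.09996723, 0.39951283, 0.70115470)),
      list(l = 1L, exps = c(3.7804559, 0.8784966, 0.2857144),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    ),
    O = list(
      list(l = 0L, exps = c(130.7093200, 23.8088610, 6.4436083),
           coefs = c(0.1543289673, 0.5353281423, 0.4446345422)),
      list(l = 0L, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = c(-0.09996723, 0.39951283, 0.70115470)),
      list(l = 1L, exps = c(5.0331513, 1.1695961, 0.3803890),
           coefs = c(0.15591627, 0.60768372, 0.39195739))
    )
  )
)

.dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

# axial primitive norm for x^l exp(-a r^2)
.prim_norm <- function(l, a) (2 * a / pi)^0.75 * (4 * a)^(l / 2) / sqrt(.dfact(2 * l - 1))

# cartesian -> real-spherical transform blocks (relative weights; absolute
# scale fixed by AO renormalization).  Cartesian order: s; x,y,z;
# xx,xy,xz,yy,yz,zz.  Spherical d order: m = -2,-1,0,+1,+2.
.sph_block <- function(l) {
  if (l == 0L) return(matrix(1, 1, 1))
  if (l == 1L) return(diag(3))
  m <- matrix(0, 6, 5)
  m[2, 1] <- 1                       # xy
  m[5, 2] <- 1                       # yz
  m[c(1, 4, 6), 3] <- c(-1, -1, 2)   # 2z^2 - x^2 - y^2
  m[3, 4] <- 1                       # xz
  m[c(1, 4), 5] <- c(1, -1)          # x^2 - y^2
  m
}

.shell_name <- function(l, idx) {
  # idx = how many shells of this l precede on the atom (0-based)
  n <- idx + 1L + l  # principal quantum number label: s from 1s, p from 2p, d from 3d
  paste0(n, c("s", "p", "d")[l + 1L])
}

#' Build a basis object for a molecule
#'
#' @param mol a [molecule()].
#' @param basis basis-set name: `"cc-pvdz"` (spherical d functions) or
#'   `"sto-3g"`.
#' @return A `basis_set` object carrying shells (centers in Bohr), the
#'   cartesian-to-spherical transform, AO normalization and AO labels.
#' @export
build_basis <- function(mol, basis = "cc-pvdz") {
  basis <- tolower(basis)
  bd <- .basis_data[[basis]]
  if (is.null(bd)) stop("unknown basis: ", basis)
  shells <- list()
  shell_atom <- integer(0)
  shell_name <- character(0)
  for (i in seq_along(mol$elements)) {
    el <- mol$elements[i]
    if (is.null(bd[[el]])) stop("basis ", basis, " has no parameters for ", el)
    cnt <- c(0L, 0L, 0L)
    for (sh in bd[[el]]) {
      l <- sh$l
      shells[[length(shells) + 1L]] <- list(
        l = l,
        center = mol$coords[i, ] / .const$bohr,
        exps = sh$exps,
        coefs = sh$coefs * vapply(sh$exps, function(a) .prim_norm(l, a), 0)
      )
      shell_atom <- c(shell_atom, i)
      shell_name <- c(shell_name, .shell_name(l, cnt[l + 1L]))
      cnt[l + 1L] <- cnt[l + 1L] + 1L
    }
  }
  ncart_per <- c(1L, 3L, 6L)[vapply(shells, `[[`, 0L, "l") + 1L]
  nsph_per <- c(1L, 3L, 5L)[vapply(shells, `[[`, 0L, "l") + 1L]
  ncart <- sum(ncart_per)
  nsph <- sum(nsph_per)
  Ct <- matrix(0, ncart, nsph)
  ic <- 0L; is <- 0L
  ao_atom <- integer(nsph); ao_label <- character(nsph)
  for (k in seq_along(shells)) {
    b <- .sph_block(shells[[k]]$l)
    Ct[ic + seq_len(nrow(b)), is + seq_len(ncol(b))] <- b
    ao_atom[is + seq_len(ncol(b))] <- shell_atom[k]
    ao_label[is + seq_len(ncol(b))] <- paste0(mol$elements[shell_atom[k]],
                                              shell_atom[k], " ", shell_name[k])
    ic <- ic + nrow(b); is <- is + ncol(b)
  }
  obj <- list(mol = mol, name = basis, shells = shells, shell_atom = shell_atom,
              shell_name = shell_name, ncart = ncart, nao = nsph, Ct = Ct,
              ao_atom = ao_atom, ao_label = ao_label, norm = NULL)
  class(obj) <- "basis_set"
  # AO renormalization from the raw cartesian overlap
  Sc <- cpp_one_electron(obj$shells, matrix(0, 0, 3), numeric(0))$S
  Ssph <- crossprod(Ct, Sc %*% Ct)
  obj$norm <- 1 / sqrt(diag(Ssph))
  obj
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("basis_set: %s, %d shells, %d spherical AOs\n",
              x$name, length(x$shells), x$nao))
  invisible(x)
}
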