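# Active-space machinery: AVAS orbital selection, frozen-core handling,
# active-space Hamiltonian extraction and FCIDUMP round trips.

#' Active space description
#'
#' @param n_electrons active electrons (even).
#' @param C_act AO coefficients of the active orbitals (columns).
#' @param C_core AO coefficients of the doubly occupied inactive orbitals.
#' @return An `active_space` object.
#' @export
active_space <- function(n_electrons, C_act, C_core) {
  if (n_electrons %% 2L != 0L) stop("active electron count must be even (closed shell)")
  n_orb <- ncol(C_act)
  if (n_orb < n_electrons / 2) stop("need n_orbitals >= n_electrons / 2")
  structure(list(n_electrons = as.integer(n_electrons),
                 n_orbitals = as.integer(n_orb),
                 n_alpha = as.integer(n_electrons / 2),
                 C_act = C_act, C_core = C_core),
            class = "active_space")
}

#' @export
print.active_space <- function(x, ...) {
  cat(sprintf("active_space: (%de,%do), %d frozen doubly occupied orbitals\n",
              x$n_electrons, x$n_orbitals, ncol(x$C_core)))
  invisible(x)
}

#' Hilbert-space dimension of an active space
#'
#' Number of determinants in the fixed (n_alpha, n_beta) sector:
#' `choose(norb, n_alpha) * choose(norb, n_beta)`.
#'
#' @param as_ an `active_space`, or a list with `n_electrons`/`n_orbitals`.
#' @return Numeric (exact integer value, possibly above 2^31).
#' @export
hilbert_dimension <- function(as_) {
  ne <- as_$n_electrons; no <- as_$n_orbitals
  if (ne %% 2 != 0) stop("odd electron counts are unsupported")
  choose(no, ne / 2)^2
}

.match_ao_labels <- function(bs, labels) {
  tok <- strsplit(bs$ao_label, " ")
  ao_atom_tag <- vapply(tok, `[[`, "", 1)        # e.g. "C1"
  ao_shell <- vapply(tok, `[[`, "", 2)           # e.g. "2s"
  ao_elem <- gsub("[0-9]+$", "", ao_atom_tag)
  idx <- integer(0)
  for (lb in labels) {
    parts <- strsplit(trimws(lb), "\\s+")[[1]]
    if (length(parts) != 2) stop("bad AO label: ", lb)
    who <- parts[1]; shell <- parts[2]
    hit <- if (grepl("[0-9]$", who)) ao_atom_tag == who & ao_shell == shell
           else ao_elem == who & ao_shell == shell
    idx <- c(idx, which(hit))
  }
  sort(unique(idx))
}

#' AVAS active-space selection
#'
#' Atomic valence active space: occupied and virtual molecular orbitals are
#' rotated separately to diagonalize their projection onto the span of the
#' chosen atomic orbitals; orbitals with projection eigenvalue above
#' `threshold` become active.
#'
#' Labels of the form `"C 2s"` select that shell on every matching atom;
#' `"C1 2s"` addresses one atom.  Labels prefixed with `"!"` switch to
#' exclusion mode: the occupied orbitals with the largest projection onto the
#' excluded shells are frozen (one per excluded function) and everything else
#' (all virtuals included) is active -- the "all orbitals minus the core"
#' construction.
#'
#' @param scf a converged `rhf_result`.
#' @param ao_labels character vector of AO labels.
#' @param threshold projection-eigenvalue threshold for selection (0.2).
#' @return An `active_space`.
#' @export
select_active_space_avas <- function(scf, ao_labels, threshold = 0.2) {
  bs <- scf$bs
  S <- scf$ints$S
  nocc <- scf$nocc
  C <- scf$C
  n <- bs$nao
  excl <- grepl("^!", ao_labels)
  if (any(excl) && !all(excl)) stop("cannot mix selection and exclusion labels")
  if (all(excl) && length(ao_labels) > 0) {
    Tix <- .match_ao_labels(bs, sub("^!", "", ao_labels))
    if (length(Tix) == 0) stop("AO exclusion list selected no functions")
    P <- S[, Tix, drop = FALSE] %*% solve(S[Tix, Tix, drop = FALSE],
                                          S[Tix, , drop = FALSE])
    Co <- C[, seq_len(nocc), drop = FALSE]
    M <- crossprod(Co, P %*% Co)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    Cr <- Co %*% e$vectors          # eigenvalues descending
    nfreeze <- length(Tix)
    C_core <- Cr[, seq_len(nfreeze), drop = FALSE]
    C_occ_act <- Cr[, -seq_len(nfreeze), drop = FALSE]
    C_vir <- C[, -seq_len(nocc), drop = FALSE]
    return(active_space(2L * (nocc - nfreeze), cbind(C_occ_act, C_vir), C_core))
  }
  Tix <- .match_ao_labels(bs, ao_labels)
  if (length(Tix) == 0) stop("AO label list selected no functions")
  P <- S[, Tix, drop = FALSE] %*% solve(S[Tix, Tix, drop = FALSE],
                                        S[Tix, , drop = FALSE])
  pick <- function(Cblk) {
    M <- crossprod(Cblk, P %*% Cblk)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    list(C = Cblk %*% e$vectors, w = e$values)  # descending
  }
  o <- pick(C[, seq_len(nocc), drop = FALSE])
  v <- pick(C[, -seq_len(nocc), drop = FALSE])
  no_act <- sum(o$w > threshold)
  nv_act <- sum(v$w > threshold)
  if (no_act == 0) stop("AVAS selected no occupied orbitals")
  C_act <- cbind(o$C[, seq_len(no_act), drop = FALSE],
                 v$C[, seq_len(nv_act), drop = FALSE])
  C_core <- o$C[, -seq_len(no_act), drop = FALSE]
  active_space(2L * no_act, C_act, C_core)
}

# 4-index AO -> MO transform (same cyclic reshape as the spherical transform)
.ao2mo <- function(eri, C) {
  arr <- eri
  m <- ncol(C)
  for (k in 1:4) {
    d <- dim(arr)
    arr <- array(crossprod(C, matrix(arr, d[1], prod(d[2:4]))), c(m, d[2], d[3], d[4]))
    arr <- aperm(arr, c(2, 3, 4, 1))
  }
  arr
}

#' Build the active-space Hamiltonian
#'
#' One- and two-electron integrals over the active orbitals with the inactive
#' (core) mean field folded into `h1` and `e_core` (which also carries the
#' nuclear repulsion).
#'
#' @param scf a converged `rhf_result` (gas phase or solvated; only orbitals
#'   are used).
#' @param as_ an `active_space`.
#' @param eri optional precomputed AO ERI tensor.
#' @return An `mo_hamiltonian`: `h1` (norb x norb), `h2` (norb^4 array,
#'   8-fold symmetric), `e_core`, electron/orbital counts and the AO-basis
#'   coefficient blocks needed to evaluate electrostatic potentials of active
#'   densities.
#' @export
build_active_hamiltonian <- function(scf, as_, eri = NULL) {
  bs <- scf$bs
  if (is.null(eri)) eri <- eri_integrals(bs)
  H <- scf$ints$H
  Cc <- as_$C_core; Ca <- as_$C_act
  if (nrow(Ca) != bs$nao) stop("inconsistent dimensions")
  ops <- .fock_ops(eri)
  if (ncol(Cc) > 0) {
    Dc <- 2 * tcrossprod(Cc)
    jk <- .build_JK(ops, Dc)
    Fc <- H + jk$J - 0.5 * jk$K
    e_core <- 0.5 * sum(Dc * (H + Fc)) + scf$ints$e_nuc
  } else {
    Fc <- H
    e_core <- scf$ints$e_nuc
  }
  h1 <- crossprod(Ca, Fc %*% Ca)
  h1 <- (h1 + t(h1)) / 2
  h2 <- .ao2mo(eri, Ca)
  structure(list(h1 = h1, h2 = h2, e_core = e_core,
                 n_electrons = as_$n_electrons, n_orbitals = as_$n_orbitals,
                 n_alpha = as_$n_alpha, C_act = Ca, C_core = Cc, bs = bs),
            class = "mo_hamiltonian")
}

#' @export
print.mo_hamiltonian <- function(x, ...) {
  cat(sprintf("mo_hamiltonian: (%de,%do), e_core = %.8f Hartree\n",
              x$n_electrons, x$n_orbitals, x$e_core))
  invisible(x)
}

#' Write an active-space Hamiltonian in FCIDUMP format
#'
#' Standard conventions: 1-based orbital indices, chemists' notation
#' integrals with 8-fold permutational symmetry, `i j 0 0` rows for h1 and a
#' final `0 0 0 0` row with the core energy.
#'
#' @param hmo an `mo_hamiltonian`.
#' @param path output file.
#' @param tol integrals below this magnitude are not written.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(hmo, path, tol = 1e-12) {
  n <- hmo$n_orbitals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("&FCI NORB=%d,NELEC=%d,MS2=0,", n, hmo$n_electrons), con)
  writeLines(paste0(" ORBSYM=", paste(rep(1, n), collapse = ","), ","), con)
  writeLines(" ISYM=1,", con)
  writeLines("&END", con)
  out <- character(0)
  for (p in 1:n) for (q in 1:p) for (r in 1:p) {
    smax <- if (r == p) q else r
    for (s in 1:smax) {
      v <- hmo$h2[p, q, r, s]
      if (abs(v) > tol)
        out <- c(out, sprintf("%23.16e %4d %4d %4d %4d", v, p, q, r, s))
    }
  }
  for (p in 1:n) for (q in 1:p) {
    v <- hmo$h1[p, q]
    if (abs(v) > tol)
      out <- c(out, sprintf("%23.16e %4d %4d %4d %4d", v, p, q, 0L, 0L))
  }
  out <- c(out, sprintf("%23.16e %4d %4d %4d %4d", hmo$e_core, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(path)
}

#' Read an FCIDUMP file
#'
#' @param path FCIDUMP file.
#' @return An `mo_hamiltonian` (without AO-basis blocks; potential hooks are
#'   unavailable for dumped Hamiltonians, so they support gas-phase
#'   diagonalization only).
#' @export
read_fcidump <- function(path) {
  ln <- readLines(path)
  hdr_end <- grep("&END|/\\s*$", ln)[1]
  hdr <- paste(ln[1:hdr_end], collapse = " ")
  n <- as.integer(sub(".*NORB\\s*=\\s*([0-9]+).*", "\\1", hdr))
  nel <- as.integer(sub(".*NELEC\\s*=\\s*([0-9]+).*", "\\1", hdr))
  body <- ln[(hdr_end + 1):length(ln)]
  body <- body[nzchar(trimws(body))]
  rows <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  val <- as.numeric(rows[, 1])
  ijkl <- matrix(as.integer(rows[, 2:5]), ncol = 4)
  h1 <- matrix(0, n, n)
  h2 <- array(0, rep(n, 4))
  e_core <- 0
  for (k in seq_along(val)) {
    p <- ijkl[k, 1]; q <- ijkl[k, 2]; r <- ijkl[k, 3]; s <- ijkl[k, 4]
    if (p == 0) { e_core <- val[k] }
    else if (r == 0) { h1[p, q] <- h1[q, p] <- val[k] }
    else {
      for (pq in list(c(p, q), c(q, p))) for (rs in list(c(r, s), c(s, r))) {
        h2[pq[1], pq[2], rs[1], rs[2]] <- val[k]
        h2[rs[1], rs[2], pq[1], pq[2]] <- val[k]
      }
    }
  }
  structure(list(h1 = h1, h2 = h2, e_core = e_core,
                 n_electrons = nel, n_orbitals = n, n_alpha = nel %/% 2L,
                 C_act = NULL, C_core = NULL, bs = NULL),
            class = "mo_hamiltonian")
}
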