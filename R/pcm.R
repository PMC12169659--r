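# IEF-PCM boundary-element solver.
#
# The cavity is a union of atom-centered van der Waals spheres (Bondi radii,
# scaled), each discretized with a deterministic golden-spiral quadrature.
# Points buried in another sphere are removed; points near an intersection
# seam get smoothly switched area weights, so cavity energies vary smoothly
# with geometry.  The apparent-surface-charge problem is the IEF integral
# equation [(2 pi f_eps) I - D] S sigma = (-2 pi I + D) phi with
# f_eps = (eps + 1)/(eps - 1), discretized with point charges q_k = sigma_k
# a_k, the classic diagonal regularization S_kk = 1.0694 sqrt(4 pi / a_k) and
# a D diagonal fixed row-wise by the Gauss solid-angle sum rule.

#' PCM configuration
#'
#' @param epsilon solvent dielectric constant (water default 78.3553).
#' @param radii_scale scale factor applied to the atomic radii.
#' @param points_per_sphere quadrature points per atomic sphere.
#' @param radii_set `"modified-bondi"` (Bondi with the Rowland-Taylor
#'   hydrogen radius 1.10 Angstrom; the default, matching mainstream IEF-PCM
#'   engine defaults) or `"bondi"`.
#' @param sw_width relative width of the switching region at sphere seams.
#' @return A `pcm_config` object.
#' @export
pcm_config <- function(epsilon = 78.3553, radii_scale = 1.2,
                       points_per_sphere = 302L, radii_set = "modified-bondi",
                       sw_width = 0.1) {
  stopifnot(epsilon >= 1, radii_scale > 0, points_per_sphere >= 6)
  structure(list(epsilon = epsilon, radii_scale = radii_scale,
                 points_per_sphere = as.integer(points_per_sphere),
                 radii_set = radii_set, sw_width = sw_width),
            class = "pcm_config")
}

# golden-spiral points on the unit sphere (deterministic)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t^3 * (10 - 15 * t + 6 * t^2)
}

#' Build a solute cavity
#'
#' @param mol a [molecule()].
#' @param config a [pcm_config()].
#' @param radii optional explicit per-atom radii (Angstrom, unscaled);
#'   defaults to the configured radii set.
#' @return A `pcm_cavity` object: surface `points` (Bohr), `areas` (Bohr^2),
#'   outward unit `normals`, owning `sphere` index, sphere `centers` and
#'   `radii` (Bohr).
#' @export
build_cavity <- function(mol, config = pcm_config(), radii = NULL) {
  if (is.null(radii)) radii <- element_radii(mol$elements, config$radii_set)
  rad <- radii * config$radii_scale / .const$bohr
  ctr <- mol$coords / .const$bohr
  nat <- nrow(ctr)
  u <- .sphere_points(config$points_per_sphere)
  pts <- NULL; areas <- NULL; nrm <- NULL; sph <- NULL
  for (A in seq_len(nat)) {
    p <- sweep(u * rad[A], 2, ctr[A, ], `+`)
    w <- rep(4 * pi * rad[A]^2 / config$points_per_sphere, nrow(p))
    keep <- rep(TRUE, nrow(p))
    for (B in seq_len(nat)) {
      if (B == A) next
      d <- sqrt(rowSums(sweep(p, 2, ctr[B, ])^2))
      keep <- keep & (d > rad[B])
      t <- (d - rad[B]) / (config$sw_width * rad[B])
      w <- w * .smoothstep(t)
    }
    keep <- keep & (w > 1e-12)
    if (any(keep)) {
      pts <- rbind(pts, p[keep, , drop = FALSE])
      areas <- c(areas, w[keep])
      nrm <- rbind(nrm, u[keep, , drop = FALSE])
      sph <- c(sph, rep(A, sum(keep)))
    }
  }
  if (is.null(pts) || nrow(pts) == 0) stop("cavity has no exposed surface points")
  structure(list(points = pts, areas = areas, normals = nrm, sphere = sph,
                 centers = ctr, radii = rad, config = config),
            class = "pcm_cavity")
}

#' @export
print.pcm_cavity <- function(x, ...) {
  cat(sprintf("pcm_cavity: %d spheres, %d surface points, exposed area %.2f Bohr^2\n",
              nrow(x$centers), nrow(x$points), sum(x$areas)))
  invisible(x)
}

#' Assemble the IEF-PCM boundary operators
#'
#' @param cavity a `pcm_cavity`.
#' @param epsilon solvent dielectric constant (>= 1).
#' @return A `pcm_operators` object with the single-layer matrix `S`, the
#'   double-layer matrix `D`, area weights, `f_eps` and `epsilon`.
#' @export
assemble_operators <- function(cavity, epsilon) {
  stopifnot(epsilon >= 1)
  p <- cavity$points
  n <- nrow(p)
  dx <- outer(p[, 1], p[, 1], `-`)
  dy <- outer(p[, 2], p[, 2], `-`)
  dz <- outer(p[, 3], p[, 3], `-`)
  r2 <- dx * dx + dy * dy + dz * dz
  if (min(r2[upper.tri(r2)]) < 1e-16) stop("coincident surface points")
  r <- sqrt(r2); diag(r) <- 1
  S <- 1 / r
  diag(S) <- 1.0694 * sqrt(4 * pi / cavity$areas)
  # D[k, j] = n_j . (s_k - s_j) / r^3   (source derivative along the normal);
  # dx[k, j] = p_k - p_j and rep(, each = n) lays n_j across columns
  nr <- cavity$normals
  Dm <- (dx * rep(nr[, 1], each = n) + dy * rep(nr[, 2], each = n) +
         dz * rep(nr[, 3], each = n)) / r^3
  diag(Dm) <- 0
  aw <- cavity$areas
  # Gauss solid-angle sum rule fixes the diagonal row-wise
  diag(Dm) <- (-2 * pi - as.vector(Dm %*% aw)) / aw
  f_eps <- if (is.finite(epsilon)) (epsilon + 1) / (epsilon - 1) else 1
  structure(list(S = S, D = Dm, areas = aw, epsilon = epsilon, f_eps = f_eps,
                 cavity = cavity),
            class = "pcm_operators")
}

#' Solve for the apparent surface charges
#'
#' Solves the discretized IEF equation for the point charges `q_k = sigma_k
#' a_k` induced by the solute potential `phi` at the surface points.
#'
#' @param ops a `pcm_operators`.
#' @param phi solute electrostatic potential at the surface points (a.u.).
#' @return A `surface_charge` object with charges `q`, charge densities
#'   `sigma`, the generating potential and the relative residual.
#' @export
solve_surface_charge <- function(ops, phi) {
  n <- length(ops$areas)
  if (length(phi) != n) stop("potential and operator point sets differ")
  if (ops$epsilon == 1) {
    return(structure(list(q = numeric(n), sigma = numeric(n), phi = phi,
                          residual = 0), class = "surface_charge"))
  }
  Dw <- ops$D * rep(ops$areas, each = n)  # D %*% diag(areas)
  M <- (2 * pi * ops$f_eps) * ops$S - Dw %*% ops$S
  rhs <- -2 * pi * phi + as.vector(Dw %*% phi)
  q <- tryCatch(solve(M, rhs), error = function(e)
    stop("singular IEF system; reciprocal condition estimate ",
         format(rcond(M), digits = 3)))
  res <- sqrt(sum((M %*% q - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  structure(list(q = as.vector(q), sigma = as.vector(q) / ops$areas, phi = phi,
                 residual = res), class = "surface_charge")
}

#' Polarization energy
#'
#' One half of the interaction between the apparent surface charges and the
#' generating solute potential.
#'
#' @param charges a `surface_charge`.
#' @param phi optionally a different potential; defaults to the generating one.
#' @return Scalar energy in Hartree.
#' @export
polarization_energy <- function(charges, phi = charges$phi) {
  0.5 * sum(charges$q * phi)
}

#' Solvent interaction operator
#'
#' Folds the apparent surface charges back onto the solute: the one-electron
#' AO matrix of the charge-electron attraction and the nuclei-charge
#' interaction scalar.
#'
#' @param charges a `surface_charge`.
#' @param bs a `basis_set`.
#' @param esp optional precomputed [esp_integrals()] tensor at the surface
#'   points.
#' @param cavity the `pcm_cavity` the charges live on.
#' @return List with the symmetric AO matrix `V` (electron part, Hartree) and
#'   scalar `e_nuc_int` (nuclear part).
#' @export
solvent_operator <- function(charges, bs, cavity, esp = NULL) {
  if (is.null(esp)) esp <- esp_integrals(bs, cavity$points)
  n <- bs$nao
  if (dim(esp)[3] != length(charges$q)) stop("dimension mismatch")
  Tm <- matrix(esp, n * n, length(charges$q))
  V <- matrix(-(Tm %*% charges$q), n, n)
  Z <- element_Z(bs$mol$elements)
  xyz <- bs$mol$coords / .const$bohr
  e_nuc_int <- 0
  for (A in seq_len(nrow(xyz))) {
    r <- sqrt(rowSums(sweep(cavity$points, 2, xyz[A, ])^2))
    e_nuc_int <- e_nuc_int + Z[A] * sum(charges$q / r)
  }
  list(V = (V + t(V)) / 2, e_nuc_int = e_nuc_int)
}

# ---- precomputed PCM state used inside SCF / SCRF loops ------------------

#' Precompute the PCM machinery for a basis set
#'
#' Builds the cavity, factorizes the IEF response so that charges follow from
#' a single matrix-vector product, and precomputes the surface-potential
#' integrals.
#'
#' @param config a [pcm_config()].
#' @param bs a `basis_set`.
#' @return A `pcm_state` list used by [pcm_field()].
#' @export
pcm_precompute <- function(config, bs) {
  cavity <- build_cavity(bs$mol, config)
  ops <- assemble_operators(cavity, config$epsilon)
  n <- bs$nao
  npts <- nrow(cavity$points)
  esp <- esp_integrals(bs, cavity$points)
  Tm <- matrix(esp, n * n, npts)
  Z <- element_Z(bs$mol$elements)
  xyz <- bs$mol$coords / .const$bohr
  phi_nuc <- numeric(npts)
  for (A in seq_len(nrow(xyz))) {
    r <- sqrt(rowSums(sweep(cavity$points, 2, xyz[A, ])^2))
    phi_nuc <- phi_nuc + Z[A] / r
  }
  K <- NULL
  if (config$epsilon > 1) {
    Dw <- ops$D * rep(ops$areas, each = npts)
    M <- (2 * pi * ops$f_eps) * ops$S - Dw %*% ops$S
    K <- solve(M, -2 * pi * diag(npts) + Dw)
  }
  list(config = config, bs = bs, cavity = cavity, ops = ops, Tm = Tm,
       phi_nuc = phi_nuc, K = K)
}

#' Reaction field of an AO density
#'
#' Given the total AO density matrix (electron number = trace with overlap),
#' computes the surface potential, solves for the charges and returns the
#' one-electron reaction-field operator and the polarization energy.
#'
#' @param state a `pcm_state` from [pcm_precompute()].
#' @param D total AO density matrix.
#' @return List with AO matrix `V`, charges `q`, surface potential `phi` and
#'   polarization energy `e_pol` = 1/2 q . phi.
#' @export
pcm_field <- function(state, D) {
  npts <- length(state$phi_nuc)
  phi_el <- -as.vector(crossprod(state$Tm, as.vector(D)))
  phi <- state$phi_nuc + phi_el
  if (is.null(state$K)) {
    q <- numeric(npts)
  } else {
    q <- as.vector(state$K %*% phi)
  }
  n <- state$bs$nao
  V <- matrix(-(state$Tm %*% q), n, n)
  V <- (V + t(V)) / 2
  list(V = V, q = q, phi = phi, e_pol = 0.5 * sum(q * phi))
}

#' Write a cavity surface dump
#'
#' Per-point CSV with positions (Angstrom), areas (Angstrom^2), outward
#' normals and, optionally, the apparent surface charge densities.
#'
#' @param cavity a `pcm_cavity`.
#' @param path output CSV path.
#' @param charges optional `surface_charge` on the same point set.
#' @return `path`, invisibly.
#' @export
write_cavity_csv <- function(cavity, path, charges = NULL) {
  b <- .const$bohr
  df <- data.frame(x = cavity$points[, 1] * b, y = cavity$points[, 2] * b,
                   z = cavity$points[, 3] * b, area = cavity$areas * b^2,
                   nx = cavity$normals[, 1], ny = cavity$normals[, 2],
                   nz = cavity$normals[, 3])
  df$sigma <- if (!is.null(charges)) charges$sigma else 0
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
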