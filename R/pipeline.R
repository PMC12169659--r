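# End-to-end orchestration: configuration container, the CASCI IEF-PCM
# reference mode, the sampled SQD IEF-PCM run (LUCJ sampling -> noise ->
# S-CORE recovery -> per-batch SCRF diagonalization), sample-size sweeps and
# packaged toy fixtures.

.default_avas <- list(
  methanol    = c("C 2s", "C 2p", "O 2s", "O 2p", "H 1s"),
  ethanol     = c("C 2s", "C 2p", "O 2s", "O 2p", "H 1s"),
  methylamine = c("C 2s", "C 2p", "N 2s", "N 2p", "H 1s"),
  water       = c("!O 1s")
)

#' Run configuration
#'
#' Collects every knob of a run; defaults mirror the reference study setup
#' (3 S-CORE iterations, 10 batches, 2e5 shots, water dielectric 78.3553).
#'
#' @param molecule_source path to an XYZ file or a built-in species name.
#' @param basis basis-set name.
#' @param active AVAS AO labels (character vector), a
#'   `list(frozen = k, n_orbitals = m)` explicit window, or `NULL` to use the
#'   packaged default labels for built-in species.
#' @param epsilon solvent dielectric; 1 = gas phase.
#' @param radii_scale,points_per_sphere cavity discretization.
#' @param shots LUCJ samples to draw.
#' @param p_flip bit-flip probability of the noise emulator.
#' @param sample_file optional pre-drawn sample file (replaces the sampler).
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param score_iterations S-CORE iterations.
#' @param n_batches number of batches K.
#' @param batch_size configurations drawn per batch.
#' @param tol_E,tol_q,davidson_tol solver tolerances.
#' @param max_dim memory cap on determinant-sector dimension.
#' @param outdir optional output directory for result records.
#' @return A `run_config`.
#' @export
run_config <- function(molecule_source, basis = "cc-pvdz", active = NULL,
                       epsilon = 78.3553, radii_scale = 1.2,
                       points_per_sphere = 302L,
                       shots = 2e5, p_flip = 0, sample_file = NULL, seed = 1L,
                       score_iterations = 3L, n_batches = 10L,
                       batch_size = 300L,
                       tol_E = 1e-8, tol_q = 1e-6, davidson_tol = 1e-8,
                       max_dim = 1e7, outdir = NULL) {
  stopifnot(shots > 0, score_iterations >= 1, n_batches >= 1, batch_size >= 1)
  if (is.null(active) && molecule_source %in% names(.default_avas))
    active <- .default_avas[[molecule_source]]
  structure(as.list(environment()), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in setdiff(names(x), "active"))
    if (!is.null(x[[k]])) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  cat(sprintf("  %-18s %s\n", "active",
              if (is.character(x$active)) paste(x$active, collapse = ", ")
              else paste(unlist(x$active), collapse = "/")))
  invisible(x)
}

.resolve_molecule <- function(config) {
  src <- config$molecule_source
  if (file.exists(src)) read_xyz(src) else builtin_molecule(src)
}

#' Explicit frozen-core orbital window
#'
#' Active space from an energy-ordered window: freeze the lowest `frozen`
#' occupied orbitals, keep the next `n_orbitals` orbitals active.
#'
#' @param scf converged `rhf_result`.
#' @param frozen number of frozen doubly occupied orbitals.
#' @param n_orbitals active orbital count.
#' @return An `active_space`.
#' @export
active_space_window <- function(scf, frozen, n_orbitals) {
  nocc <- scf$nocc
  if (frozen >= nocc) stop("cannot freeze all occupied orbitals")
  if (frozen + n_orbitals > ncol(scf$C)) stop("window exceeds orbital count")
  active_space(2L * (nocc - frozen),
               scf$C[, (frozen + 1L):(frozen + n_orbitals), drop = FALSE],
               scf$C[, seq_len(frozen), drop = FALSE])
}

.make_active <- function(scf, active) {
  if (is.character(active)) select_active_space_avas(scf, active)
  else if (is.list(active)) active_space_window(scf, active$frozen, active$n_orbitals)
  else stop("no active-space specification")
}

# shared chemistry stage: SCF (solvated if eps > 1), active space, integrals
.chem_stage <- function(config) {
  mol <- .resolve_molecule(config)
  bs <- build_basis(mol, config$basis)
  ints <- one_electron_integrals(bs)
  eri <- eri_integrals(bs)
  pcm <- if (config$epsilon > 1)
    pcm_config(epsilon = config$epsilon, radii_scale = config$radii_scale,
               points_per_sphere = config$points_per_sphere) else NULL
  scf <- rhf(bs, pcm = pcm, ints = ints, eri = eri)
  as_ <- .make_active(scf, config$active)
  hmo <- build_active_hamiltonian(scf, as_, eri = eri)
  pcm_state <- if (!is.null(pcm)) pcm_precompute(pcm, bs) else NULL
  list(mol = mol, bs = bs, ints = ints, eri = eri, pcm = pcm,
       pcm_state = pcm_state, scf = scf, active = as_, hmo = hmo)
}

.gas_reference_energy <- function(config, chem) {
  # full gas-phase pipeline at the same geometry: gas RHF -> same active-space
  # rule -> full-sector diagonalization
  scf_g <- rhf(chem$bs, pcm = NULL, ints = chem$ints, eri = chem$eri)
  as_g <- .make_active(scf_g, config$active)
  hmo_g <- build_active_hamiltonian(scf_g, as_g, eri = chem$eri)
  sub <- full_sector(as_g$n_orbitals, as_g$n_alpha)
  ci_ground_state(project_hamiltonian(hmo_g, sub), tol = config$davidson_tol)$energy
}

#' CASCI IEF-PCM reference calculation
#'
#' Full-sector SCRF diagonalization: the classical reference the sampled
#' method is judged against.  Solvation free energies are reported under both
#' conventions: `gsolv` = G(solution) - E(gas), with the gas energy from the
#' full gas-phase pipeline at the same geometry, and `gsolv_polarization` =
#' the converged polarization energy alone.
#'
#' @param config a [run_config()].
#' @return A `casci_reference` record.
#' @export
run_casci_reference <- function(config) {
  chem <- .chem_stage(config)
  D <- hilbert_dimension(chem$active)
  if (D > config$max_dim)
    stop(sprintf("full sector dimension %.4g exceeds the memory cap %.4g",
                 D, config$max_dim))
  sub <- full_sector(chem$active$n_orbitals, chem$active$n_alpha)
  res <- solve_scrf_ground_state(chem$hmo, sub, pcm = chem$pcm_state,
                                 tol_E = config$tol_E, tol_q = config$tol_q,
                                 davidson_tol = config$davidson_tol)
  e_gas_pipeline <- if (config$epsilon > 1) .gas_reference_energy(config, chem) else res$E
  gv <- if (config$epsilon > 1) gsolv(res, e_gas_pipeline) else
    list(gsolv = 0, gsolv_polarization = 0)
  out <- structure(list(
    config = config, result = res, E = res$E, E_gas = e_gas_pipeline,
    E_gas_same_orbitals = res$E_gas,
    gsolv = gv$gsolv, gsolv_polarization = gv$gsolv_polarization,
    gsolv_same_orbitals = if (config$epsilon > 1)
      (res$E - res$E_gas) * .const$hartree_kcal else 0,
    active = c(chem$active$n_electrons, chem$active$n_orbitals),
    hilbert_dimension = D, scf_energy = chem$scf$energy),
    class = "casci_reference")
  .write_outputs(config, list(kind = "casci_reference", record = .record_of(out)))
  out
}

#' @export
print.casci_reference <- function(x, ...) {
  cat(sprintf("CASCI%s reference: (%de,%do), D = %s\n",
              if (x$config$epsilon > 1) " IEF-PCM" else "",
              x$active[1], x$active[2],
              format(x$hilbert_dimension, big.mark = ",")))
  cat(sprintf("  G = %.8f Hartree; G_solv = %.3f kcal/mol (polarization %.3f)\n",
              x$E, x$gsolv, x$gsolv_polarization))
  invisible(x)
}

# one S-CORE + batch-solve pass over prepared samples
.sqd_solve <- function(config, chem, noisy, verbose = FALSE) {
  na <- chem$active$n_alpha
  occ <- initial_occupancy(noisy, na, na)
  results <- NULL
  for (it in seq_len(config$score_iterations)) {
    rec <- recover_configurations(noisy, occ, na, na,
                                  seed = config$seed + 7919L * it)
    batches <- partition_batches(rec, config$n_batches, config$batch_size,
                                 seed = config$seed + 7919L * it + 1L)
    results <- lapply(batches, function(bt) {
      sub <- close_under_spin_inversion(bt, chem$active$n_orbitals, na)
      r <- solve_scrf_ground_state(chem$hmo, sub, pcm = chem$pcm_state,
                                   tol_E = config$tol_E, tol_q = config$tol_q,
                                   davidson_tol = config$davidson_tol)
      r$chi_b <- nrow(bt)
      r
    })
    occ <- update_occupancy(results)
    if (verbose)
      message(sprintf("  S-CORE iteration %d: best E = %.8f", it,
                      min(vapply(results, function(r) r$E, 0))))
  }
  list(results = results, occ = occ, recovered = rec)
}

#' Run the sampled SQD IEF-PCM workflow
#'
#' Chemistry setup, gas-phase CCSD-parametrized LUCJ sampling (or a sample
#' file), noise injection, S-CORE recovery and per-batch SCRF
#' diagonalization; the lowest-energy batch provides the reported energy and
#' solvation free energy.
#'
#' @param config a [run_config()].
#' @param reference also run the full-sector CASCI(-PCM) reference for the
#'   deviation column (requires the sector to fit the memory cap).
#' @param verbose print stage progress.
#' @return An `sqd_run` record.
#' @export
run_sqd_pcm <- function(config, reference = FALSE, verbose = FALSE) {
  chem <- .chem_stage(config)
  na <- chem$active$n_alpha
  if (!is.null(config$sample_file)) {
    raw <- read_sample_file(config$sample_file, norb = chem$active$n_orbitals)
    noisy <- raw
  } else {
    cc <- ccsd(chem$hmo)   # gas-phase amplitudes: hmo carries no V_int
    par <- derive_lucj_from_ccsd(cc, chem$active$n_orbitals)
    st <- simulate_lucj_state(par, na, max_dim = config$max_dim)
    raw <- sample_bitstrings(st, config$shots, seed = config$seed)
    noisy <- if (config$p_flip > 0)
      inject_noise(raw, config$p_flip, seed = config$seed + 1L) else raw
  }
  sq <- .sqd_solve(config, chem, noisy, verbose = verbose)
  best <- select_best_batch(sq$results)
  gv <- gsolv(best)
  ref <- NULL
  if (reference) {
    sub <- full_sector(chem$active$n_orbitals, na)
    ref <- solve_scrf_ground_state(chem$hmo, sub, pcm = chem$pcm_state,
                                   tol_E = config$tol_E, tol_q = config$tol_q,
                                   davidson_tol = config$davidson_tol)
  }
  curve_row <- data.frame(
    chi_b = best$chi_b, d = best$d, E_sqd = best$E,
    E_casci = if (!is.null(ref)) ref$E else NA_real_,
    dE_kcal = if (!is.null(ref)) (best$E - ref$E) * .const$hartree_kcal else NA_real_,
    gsolv = gv$gsolv)
  out <- structure(list(
    config = config, best = best, batches = sq$results,
    occupancies = sq$occ, reference = ref, curve_row = curve_row,
    gsolv = gv$gsolv, gsolv_polarization = gv$gsolv_polarization,
    E = best$E, batch_energies = vapply(sq$results, function(r) r$E, 0),
    d = best$d, chi_b = best$chi_b, noisy_shots = noisy$shots),
    class = "sqd_run")
  .write_outputs(config, list(kind = "sqd_run", record = .record_of(out)))
  out
}

#' @export
print.sqd_run <- function(x, ...) {
  cat(sprintf("sqd_run: best batch %d/%d, |chi_b| = %d, d = %s\n",
              x$best$batch, length(x$batches), x$chi_b,
              format(x$d, big.mark = ",")))
  cat(sprintf("  E = %.8f Hartree, G_solv = %.3f kcal/mol\n", x$E, x$gsolv))
  if (!is.na(x$curve_row$dE_kcal))
    cat(sprintf("  deviation vs CASCI reference: %.3f kcal/mol\n",
                x$curve_row$dE_kcal))
  invisible(x)
}

#' Sweep the batch sample size
#'
#' Repeats the S-CORE + solve stage over ascending batch sizes with shared
#' upstream artifacts (one SCF, one sampler draw) and collects the
#' convergence curve; the CASCI(-PCM) reference is computed once.
#'
#' @param config a [run_config()]; its `batch_size` is overridden.
#' @param sizes ascending batch sizes.
#' @param reference include the full-sector reference column.
#' @param verbose print stage progress.
#' @return A `convergence_curve` data.frame with one row per size.
#' @export
sweep_sample_size <- function(config, sizes, reference = TRUE, verbose = FALSE) {
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  chem <- .chem_stage(config)
  na <- chem$active$n_alpha
  if (!is.null(config$sample_file)) {
    noisy <- read_sample_file(config$sample_file, norb = chem$active$n_orbitals)
  } else {
    cc <- ccsd(chem$hmo)
    par <- derive_lucj_from_ccsd(cc, chem$active$n_orbitals)
    st <- simulate_lucj_state(par, na, max_dim = config$max_dim)
    raw <- sample_bitstrings(st, config$shots, seed = config$seed)
    noisy <- if (config$p_flip > 0)
      inject_noise(raw, config$p_flip, seed = config$seed + 1L) else raw
  }
  ref <- NULL
  if (reference) {
    sub <- full_sector(chem$active$n_orbitals, na)
    ref <- solve_scrf_ground_state(chem$hmo, sub, pcm = chem$pcm_state,
                                   tol_E = config$tol_E, tol_q = config$tol_q,
                                   davidson_tol = config$davidson_tol)
  }
  rows <- lapply(sizes, function(bsz) {
    cfg <- config; cfg$batch_size <- as.integer(bsz)
    sq <- .sqd_solve(cfg, chem, noisy, verbose = verbose)
    best <- select_best_batch(sq$results)
    gv <- gsolv(best)
    data.frame(chi_b = best$chi_b, d = best$d, E_sqd = best$E,
               E_casci = if (!is.null(ref)) ref$E else NA_real_,
               dE_kcal = if (!is.null(ref))
                 (best$E - ref$E) * .const$hartree_kcal else NA_real_,
               gsolv = gv$gsolv)
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("convergence_curve", class(curve))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(curve),
                     file.path(config$outdir, "convergence_curve.csv"),
                     row.names = FALSE)
  }
  curve
}

#' Generate a packaged toy fixture
#'
#' Emits the XYZ geometry, a YAML run configuration and (optionally) a
#' pre-drawn sample file for one of the self-contained toy systems:
#' `"h2"` (2e,2o minimal basis), `"h2o-mini"` (water, STO-3G, (6e,5o)),
#' `"h6"` (linear chain, STO-3G, (6e,6o)).
#'
#' @param kind fixture name.
#' @param seed RNG seed for the sample draw.
#' @param dir output directory.
#' @param with_samples also draw and write a noiseless sample file.
#' @param shots shots for the sample file.
#' @return Invisibly, the list of written paths.
#' @export
generate_fixture <- function(kind, seed = 1L, dir = ".", with_samples = FALSE,
                             shots = 5e4) {
  kinds <- c("h2", "h2o-mini", "h6")
  if (!kind %in% kinds)
    stop("unknown fixture kind; available: ", paste(kinds, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mol <- builtin_molecule(kind)
  xyz <- file.path(dir, paste0(gsub("-", "_", kind), ".xyz"))
  write_xyz(mol, xyz, comment = paste(kind, "toy fixture"))
  active <- switch(kind,
    "h2" = list(frozen = 0L, n_orbitals = 2L),
    "h2o-mini" = list(frozen = 2L, n_orbitals = 5L),
    "h6" = list(frozen = 0L, n_orbitals = 6L))
  cfgpath <- file.path(dir, paste0(gsub("-", "_", kind), "_config.yaml"))
  cfg <- list(molecule_source = xyz, basis = "sto-3g", active = active,
              epsilon = 78.3553, shots = shots, p_flip = 0.02,
              seed = as.integer(seed), score_iterations = 3L, n_batches = 10L,
              batch_size = 20L)
  yaml::write_yaml(cfg, cfgpath)
  paths <- c(xyz, cfgpath)
  if (with_samples) {
    rc <- do.call(run_config, cfg)
    chem <- .chem_stage(rc)
    cc <- ccsd(chem$hmo)
    par <- derive_lucj_from_ccsd(cc, chem$active$n_orbitals)
    st <- simulate_lucj_state(par, chem$active$n_alpha)
    raw <- sample_bitstrings(st, shots, seed = seed)
    spath <- file.path(dir, paste0(gsub("-", "_", kind), "_samples.txt"))
    write_sample_file(raw, spath)
    paths <- c(paths, spath)
  }
  invisible(paths)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$active) && is.list(y$active))
    y$active <- list(frozen = as.integer(y$active$frozen),
                     n_orbitals = as.integer(y$active$n_orbitals))
  do.call(run_config, y)
}

# ---- result records ------------------------------------------------------

.record_of <- function(x) {
  cfg <- x$config
  cfg$outdir <- NULL
  rec <- list(
    package = "sqdpcm",
    version = as.character(utils::packageVersion("sqdpcm")),
    config = cfg[!vapply(cfg, is.null, TRUE)])
  if (inherits(x, "casci_reference")) {
    rec <- c(rec, x[c("E", "E_gas", "E_gas_same_orbitals", "gsolv",
                      "gsolv_polarization", "gsolv_same_orbitals",
                      "hilbert_dimension")],
             list(active = x$active, scrf_log = x$result$scrf_log))
  } else {
    rec <- c(rec, x[c("E", "gsolv", "gsolv_polarization", "d", "chi_b",
                      "batch_energies")],
             list(best_batch = x$best$batch,
                  scrf_log = x$best$scrf_log))
  }
  rec$config_hash <- .config_hash(cfg)
  rec
}

.config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small deterministic polynomial hash; avoids external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.write_outputs <- function(config, payload) {
  if (is.null(config$outdir)) return(invisible(NULL))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$outdir, paste0(payload$kind, ".json"))
  jsonlite::write_json(payload$record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
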