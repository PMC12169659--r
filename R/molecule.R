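# Molecular geometry container and XYZ i/o.
#
# Coordinates are stored in Angstrom (the unit of XYZ files); integral and
# energy code converts to Bohr internally.  Only neutral closed-shell species
# are supported by the solvated-diagonalization workflow.

.elements <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"),
  Z      = 1:10,
  # Bondi van der Waals radii (Angstrom)
  bondi  = c(1.20, 1.40, 1.81, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54),
  # modified Bondi: Rowland-Taylor hydrogen radius, otherwise Bondi
  bondi_mod = c(1.10, 1.40, 1.81, 1.53, 1.92, 1.70, 1.55, 1.52, 1.47, 1.54),
  stringsAsFactors = FALSE
)

element_Z <- function(sym) {
  i <- match(sym, .elements$symbol)
  if (anyNA(i)) stop("unknown element symbol(s): ", paste(sym[is.na(i)], collapse = ", "))
  .elements$Z[i]
}

element_radii <- function(sym, set = "modified-bondi") {
  i <- match(sym, .elements$symbol)
  if (anyNA(i)) stop("unknown element symbol(s): ", paste(sym[is.na(i)], collapse = ", "))
  switch(set,
         "bondi" = .elements$bondi[i],
         "modified-bondi" = .elements$bondi_mod[i],
         stop("unknown radii set: ", set))
}

#' Construct a molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge total charge; only 0 is supported by the workflow.
#' @param multiplicity spin multiplicity; only 1 (closed shell) is supported.
#' @return An object of class `molecule`.
#' @export
molecule <- function(elements, coords, charge = 0L, multiplicity = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(elements))
    stop("element count must equal coordinate row count")
  if (ncol(coords) != 3) stop("coords must be n x 3")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (charge != 0L || multiplicity != 1L)
    stop("only neutral closed-shell solutes (charge 0, multiplicity 1) are supported")
  structure(list(elements = as.character(elements), coords = coords,
                 charge = as.integer(charge), multiplicity = as.integer(multiplicity)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s), charge %d, multiplicity %d\n",
              length(x$elements), paste(x$elements, collapse = ""),
              x$charge, x$multiplicity))
  for (i in seq_along(x$elements))
    cat(sprintf("  %-2s %12.6f %12.6f %12.6f\n", x$elements[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  invisible(x)
}

n_electrons <- function(mol) sum(element_Z(mol$elements)) - mol$charge

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' `symbol x y z` row per atom (Angstrom).
#'
#' @param path file path.
#' @return A `molecule`.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  molecule(el, xyz)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a `molecule`.
#' @param path output file path.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(mol$elements)), comment), con)
  for (i in seq_along(mol$elements))
    writeLines(sprintf("%-2s %16.10f %16.10f %16.10f", mol$elements[i],
                       mol$coords[i, 1], mol$coords[i, 2], mol$coords[i, 3]), con)
  invisible(path)
}

#' Built-in solute geometries
#'
#' Returns the packaged geometry for a named species.  The polar solutes
#' (`methanol`, `methylamine`, `ethanol`, `water`) are shipped as RHF/cc-pVDZ
#' IEF-PCM (water) optimized structures produced with [optimize_geometry()];
#' the toy systems (`h2`, `h6`, `h2o-mini`) are fixed reference geometries for
#' the test ladder.
#'
#' @param species one of `"methanol"`, `"methylamine"`, `"ethanol"`,
#'   `"water"`, `"h2"`, `"h6"`, `"h2o-mini"`.
#' @return A `molecule`.
#' @export
builtin_molecule <- function(species) {
  path <- system.file("extdata", paste0(gsub("-", "_", species), ".xyz"),
                      package = "sqdpcm")
  if (!nzchar(path)) stop("unknown built-in species: ", species)
  read_xyz(path)
}
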