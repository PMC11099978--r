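#' @useDynLib rdmft, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats uniroot qnorm pnorm dnorm rnorm runif
NULL

# bohr per Angstrom
.angstrom <- 1.8897259886

.element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18
)

#' Construct a molecule
#'
#' A closed-shell molecule: element symbols, cartesian coordinates in
#' Angstrom, and a total charge.  The electron count is derived from the
#' atomic numbers minus the charge and must be even (restricted scope).
#'
#' @param atoms character vector of element symbols.
#' @param coordinates numeric matrix, one row per atom, columns x, y, z in
#'   Angstrom.
#' @param charge integer total charge (default 0).
#' @return An object of class `rdmft_molecule` with fields `atoms`,
#'   `coordinates` (Angstrom), `charge`, `n_electrons` and `atomic_numbers`.
#' @export
molecule <- function(atoms, coordinates, charge = 0L) {
  atoms <- as.character(atoms)
  coordinates <- matrix(as.numeric(coordinates), nrow = length(atoms), ncol = 3)
  unknown <- setdiff(atoms, names(.element_numbers))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  z <- unname(.element_numbers[atoms])
  ne <- sum(z) - charge
  if (ne <= 0) stop("non-positive electron count")
  if (ne %% 2 != 0) {
    stop("unsupported system: odd electron count (", ne,
         "); only closed-shell molecules are handled")
  }
  structure(
    list(atoms = atoms, coordinates = coordinates, charge = as.integer(charge),
         n_electrons = as.integer(ne), atomic_numbers = z),
    class = "rdmft_molecule"
  )
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: atom count on the first line, a comment line, then
#' one `element x y z` line per atom with coordinates in Angstrom.
#'
#' @param path path to the XYZ file.
#' @param charge integer total charge (XYZ carries none; default 0).
#' @return An `rdmft_molecule`.
#' @export
load_geometry <- function(path, charge = 0L) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("malformed XYZ: empty file ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("malformed XYZ at line 1: expected an atom count, got '", lines[1], "'")
  }
  if (length(lines) < n + 2) {
    stop("malformed XYZ: header announces ", n, " atoms but file has only ",
         max(0, length(lines) - 2), " atom lines")
  }
  atoms <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- n_line <- i + 2
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 4) {
      stop("malformed XYZ at line ", ln, ": expected 'element x y z', got '",
           lines[ln], "'")
    }
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (any(is.na(xyz))) {
      stop("malformed XYZ at line ", ln, ": non-numeric coordinate in '",
           lines[ln], "'")
    }
    atoms[i] <- toks[1]
    coords[i, ] <- xyz
  }
  molecule(atoms, coords, charge = charge)
}

#' Nuclear repulsion energy (Hartree)
#'
#' @param mol an `rdmft_molecule`.
#' @return scalar nuclear-nuclear repulsion in Hartree.
#' @export
nuclear_repulsion <- function(mol) {
  xyz <- mol$coordinates * .angstrom
  z <- mol$atomic_numbers
  e <- 0
  n <- length(z)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e <- e + z[i] * z[j] / sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  e
}

# Built-in geometries (standard experimental equilibrium structures, Angstrom).
# Iteration counts of the optimizer are geometry-sensitive; these are the
# structures used throughout the package's examples and checks.
.builtin_geometries <- list(
  H2O = list(atoms = c("O", "H", "H"),
             coords = rbind(c(0, 0, 0.1173),
                            c(0, 0.7572, -0.4692),
                            c(0, -0.7572, -0.4692))),
  HF = list(atoms = c("H", "F"),
            coords = rbind(c(0, 0, 0), c(0, 0, 0.9168))),
  CH4 = list(atoms = c("C", "H", "H", "H", "H"),
             coords = rbind(c(0, 0, 0),
                            c(0.62758, 0.62758, 0.62758),
                            c(-0.62758, -0.62758, 0.62758),
                            c(-0.62758, 0.62758, -0.62758),
                            c(0.62758, -0.62758, -0.62758))),
  H2 = list(atoms = c("H", "H"),
            coords = rbind(c(0, 0, 0), c(0, 0, 0.7414))),
  N2 = list(atoms = c("N", "N"),
            coords = rbind(c(0, 0, 0), c(0, 0, 1.0977)))
)

#' Built-in equilibrium geometry
#'
#' Convenience constructor for a handful of small molecules at standard
#' experimental equilibrium geometries (H2O: r(OH) 0.9572 A, 104.52 deg;
#' HF: 0.9168 A; CH4: r(CH) 1.0870 A tetrahedral; H2: 0.7414 A;
#' N2: 1.0977 A).
#'
#' @param name one of "H2O", "HF", "CH4", "H2", "N2".
#' @param scale multiply all coordinates by this factor (bond stretching).
#' @return An `rdmft_molecule`.
#' @export
builtin_molecule <- function(name, scale = 1) {
  g <- .builtin_geometries[[name]]
  if (is.null(g)) {
    stop("no built-in geometry for '", name, "'; available: ",
         paste(names(.builtin_geometries), collapse = ", "))
  }
  molecule(g$atoms, g$coords * scale)
}
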