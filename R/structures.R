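# Molecular structure ingestion and atom typing.

.PROTEIN_ELEMENTS <- c("C", "N", "O", "S")
.LIGAND_ELEMENTS  <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H")
.METAL_ELEMENTS   <- c("Zn", "Mg", "Mn", "Ca", "Na", "Fe", "Ni")
.RESIDUE_CATEGORIES <- list(
  H = c("GLY", "ALA", "VAL", "LEU", "ILE", "MET", "PRO", "PHE", "TRP"),
  U = c("SER", "THR", "ASN", "GLN", "TYR", "CYS"),
  N = c("ASP", "GLU"),
  P = c("LYS", "ARG", "HIS"))

.KNOWN_ELEMENTS <- unique(c(.LIGAND_ELEMENTS, .METAL_ELEMENTS, "Cu", "K", "B",
                            "Si", "Se", "As", "Al", "Li", "Co", "Cr", "Cd",
                            "Hg", "Pt", "Ru"))

# normalize an element token to its standard symbol ("CL"/"cl" -> "Cl")
.normalize_element <- function(token) {
  token <- gsub("[^A-Za-z]", "", token)
  if (!nzchar(token)) return("")
  hit <- match(toupper(token), toupper(.KNOWN_ELEMENTS))
  if (!is.na(hit)) return(.KNOWN_ELEMENTS[hit])
  paste0(toupper(substr(token, 1L, 1L)),
         tolower(substr(token, 2L, nchar(token))))
}

.empty_atoms <- function() {
  data.frame(element = character(0), x = numeric(0), y = numeric(0),
              z = numeric(0), residue = character(0), role = character(0),
              stringsAsFactors = FALSE)
}

#' Bundle atoms into a molecular complex
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z`,
#'   `residue`, `role` (`role` one of `protein`, `ligand`, `metal`)
#' @param identifier text id for the complex
#' @return an object of class `molecular_complex`
#' @export
molecular_complex <- function(atoms, identifier = "complex") {
  need <- c("element", "x", "y", "z", "residue", "role")
  if (!all(need %in% names(atoms))) stop("atoms must have columns: ",
                                         paste(need, collapse = ", "))
  bad <- atoms$role == "metal" & !(atoms$element %in% .METAL_ELEMENTS)
  if (any(bad)) stop("metal role assigned to non-metal element: ",
                     paste(unique(atoms$element[bad]), collapse = ", "))
  structure(list(atoms = atoms, identifier = identifier),
            class = "molecular_complex")
}

#' @export
print.molecular_complex <- function(x, ...) {
  tab <- table(factor(x$atoms$role, levels = c("protein", "ligand", "metal")))
  cat("molecular complex '", x$identifier, "': ",
      paste(tab, names(tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read protein and metal atoms from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. ATOM records become protein
#' atoms; HETATM records whose element is one of the tracked metals
#' (Zn, Mg, Mn, Ca, Na, Fe, Ni) become metal atoms; waters (HOH) and other
#' HETATM groups are skipped (ligands are read separately with
#' [read_ligand()]). The element is taken from columns 77-78, falling back
#' to the first alphabetic character of the atom name; for alternate
#' locations only the first occurrence of each atom is kept.
#'
#' @param path PDB file path
#' @return atoms data frame (see [molecular_complex()])
#' @export
read_protein_pdb <- function(path) {
  lines <- readLines(path)
  rows <- list()
  seen <- character(0)
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    rec <- substr(line, 1L, 6L)
    is_atom <- identical(trimws(rec), "ATOM")
    is_het <- identical(trimws(rec), "HETATM")
    if (!is_atom && !is_het) next
    if (nchar(line) < 54L) {
      stop("PDB line ", ln, ": record too short for coordinates")
    }
    resname <- toupper(trimws(substr(line, 18L, 20L)))
    if (resname == "HOH") next
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31L, 38L),
                                         substr(line, 39L, 46L),
                                         substr(line, 47L, 54L))))
    if (anyNA(xyz)) stop("PDB line ", ln, ": unparseable coordinate field")
    name <- trimws(substr(line, 13L, 16L))
    elem <- .normalize_element(substr(line, 77L, 78L))
    if (!nzchar(elem)) {
      elem <- .normalize_element(substr(gsub("[^A-Za-z]", "", name), 1L, 1L))
    }
    if (!nzchar(elem)) stop("PDB line ", ln, ": cannot determine element")
    # alternate locations: first occurrence per atom identity wins
    key <- paste(substr(line, 22L, 22L), trimws(substr(line, 23L, 26L)),
                 resname, name)
    if (key %in% seen) next
    seen <- c(seen, key)
    role <- if (is_het) {
      if (elem %in% .METAL_ELEMENTS) "metal" else NA_character_
    } else "protein"
    if (is.na(role)) next
    rows[[length(rows) + 1L]] <- data.frame(
      element = elem, x = xyz[1L], y = xyz[2L], z = xyz[3L],
      residue = resname, role = role, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(.empty_atoms())
  do.call(rbind, rows)
}

#' Read ligand atoms from a MOL2 or SDF file
#'
#' All atoms are given the `ligand` role. MOL2 elements come from the SYBYL
#' atom type (the part before any dot); SDF (V2000) elements from the atom
#' block symbol field. Two-letter elements (Cl, Br, ...) are normalized.
#'
#' @param path file path ending in `.mol2`, `.sdf`, `.sd` or `.mol`
#' @return atoms data frame
#' @export
read_ligand <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mol2") return(.read_mol2(path))
  if (ext %in% c("sdf", "sd", "mol")) return(.read_sdf(path))
  stop("unsupported ligand format: .", ext, " (expected .mol2 or .sdf)")
}

.read_mol2 <- function(path) {
  lines <- readLines(path)
  start <- which(trimws(lines) == "@<TRIPOS>ATOM")
  if (length(start) == 0L) stop("MOL2: no @<TRIPOS>ATOM section")
  start <- start[1L] + 1L
  ends <- which(startsWith(trimws(lines), "@<TRIPOS>"))
  stop_at <- ends[ends >= start]
  stop_at <- if (length(stop_at) == 0L) length(lines) else stop_at[1L] - 1L
  block <- lines[start:stop_at]
  block <- block[nzchar(trimws(block))]
  if (length(block) == 0L) stop("MOL2: empty atom block")
  rows <- lapply(seq_along(block), function(k) {
    parts <- strsplit(trimws(block[k]), "\\s+")[[1L]]
    if (length(parts) < 6L) stop("MOL2 atom line ", k, ": too few fields")
    xyz <- suppressWarnings(as.numeric(parts[3:5]))
    if (anyNA(xyz)) stop("MOL2 atom line ", k, ": bad coordinates")
    elem <- .normalize_element(strsplit(parts[6L], ".", fixed = TRUE)[[1L]][1L])
    data.frame(element = elem, x = xyz[1L], y = xyz[2L], z = xyz[3L],
               residue = "", role = "ligand", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.read_sdf <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("SDF: empty molecule block")
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(natoms) || natoms < 1L) stop("SDF: empty molecule block")
  if (length(lines) < 4L + natoms) stop("SDF: truncated atom block")
  rows <- lapply(seq_len(natoms), function(k) {
    line <- lines[4L + k]
    xyz <- suppressWarnings(as.numeric(c(substr(line, 1L, 10L),
                                         substr(line, 11L, 20L),
                                         substr(line, 21L, 30L))))
    if (anyNA(xyz)) stop("SDF atom line ", k, ": bad coordinates")
    elem <- .normalize_element(substr(line, 32L, 34L))
    if (!nzchar(elem)) stop("SDF atom line ", k, ": missing element")
    data.frame(element = elem, x = xyz[1L], y = xyz[2L], z = xyz[3L],
               residue = "", role = "ligand", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Side-chain category of a standard amino acid residue
#'
#' Maps a 3-letter residue code to one of the four side-chain categories:
#' hydrophobic `H` (Gly, Ala, Val, Leu, Ile, Met, Pro, Phe, Trp), uncharged
#' `U` (Ser, Thr, Asn, Gln, Tyr, Cys), negatively charged `N` (Asp, Glu),
#' positively charged `P` (Lys, Arg, His).
#'
#' @param residue_name 3-letter code(s), case-insensitive (vectorized)
#' @return character vector of categories in `{H, U, N, P}`
#' @export
residue_category <- function(residue_name) {
  code <- toupper(trimws(residue_name))
  lut <- stats::setNames(
    rep(names(.RESIDUE_CATEGORIES), lengths(.RESIDUE_CATEGORIES)),
    unlist(.RESIDUE_CATEGORIES))
  out <- lut[code]
  if (anyNA(out)) {
    stop("unknown residue code: ", paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Extract the binding pocket of a molecular complex
#'
#' Keeps every ligand atom, protein atoms whose minimum distance to any
#' ligand atom is at most `protein_cutoff` (12 A default), and metal atoms
#' within `metal_cutoff` (15 A default) of the ligand. Comparisons are
#' closed (`<=`). Idempotent.
#'
#' @param mc a `molecular_complex` with at least one ligand atom
#' @param protein_cutoff protein-ligand atom-atom distance cutoff (A)
#' @param metal_cutoff metal-ligand distance cutoff (A)
#' @return a pocket `molecular_complex`
#' @export
pocket_atoms <- function(mc, protein_cutoff = 12, metal_cutoff = 15) {
  at <- mc$atoms
  lig <- at[at$role == "ligand", , drop = FALSE]
  if (nrow(lig) == 0L) stop("no ligand atoms in complex")
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])
  mind <- function(rows) {
    if (nrow(rows) == 0L) return(numeric(0))
    CD <- .cross_dist(as.matrix(rows[, c("x", "y", "z")]), lig_xyz)
    apply(CD, 1L, min)
  }
  keep <- logical(nrow(at))
  keep[at$role == "ligand"] <- TRUE
  ip <- which(at$role == "protein")
  keep[ip] <- mind(at[ip, , drop = FALSE]) <= protein_cutoff
  im <- which(at$role == "metal")
  keep[im] <- mind(at[im, , drop = FALSE]) <= metal_cutoff
  molecular_complex(at[keep, , drop = FALSE], mc$identifier)
}
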