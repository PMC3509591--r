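# All-atom structure input. PDB records are parsed with bio3d; this layer
# normalises them to the package's unit conventions (nm) and applies the
# altloc / non-standard-residue policy.

#' Read an all-atom protein structure from a PDB file
#'
#' Only the first model is used. Alternate locations are resolved to the
#' highest-occupancy (ties: first listed) conformer. Residues outside the 20
#' standard amino acids are skipped with a warning; water molecules
#' (`HOH`/`SOL`/`WAT`) are collected separately as their oxygen positions.
#'
#' @param file Path to a PDB file.
#' @return An `aa_structure`: a list with `atoms` (data frame with `chain`,
#'   `resno`, `resid`, `elety` (atom name), `element`, `x`, `y`, `z` in nm,
#'   `mass` in amu), and `water_o` (matrix of water oxygen positions, nm).
#' @seealso [parse_structure()] to parse PDB text directly,
#'   [map_structure()] for the coarse-grained mapping.
#' @export
read_structure <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  atoms <- pdb$atom
  .normalize_atoms(atoms)
}

#' Parse PDB text into an all-atom structure
#'
#' @param pdb_text Character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @return An `aa_structure`; see [read_structure()].
#' @export
parse_structure <- function(pdb_text) {
  if (length(pdb_text) == 1L && grepl("\n", pdb_text))
    pdb_text <- strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(pdb_text, tmp)
  read_structure(tmp)
}

.element_from_atom <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the first letter of the atom name that is not a digit
    guess <- sub("^[0-9]*", "", trimws(elety[miss]))
    el[miss] <- substr(guess, 1L, 1L)
  }
  el
}

.normalize_atoms <- function(atoms) {
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  resid <- toupper(trimws(atoms$resid))

  is_water <- resid %in% WATER_RESIDUES
  water <- atoms[is_water, , drop = FALSE]
  water_o <- water[toupper(substr(trimws(water$elety), 1, 1)) == "O",
                   c("x", "y", "z"), drop = FALSE]
  water_o <- as.matrix(water_o) / 10  # A -> nm

  atoms <- atoms[!is_water, , drop = FALSE]
  resid <- resid[!is_water]
  nonstd <- !(resid %in% STANDARD_RESIDUES)
  if (any(nonstd)) {
    skipped <- unique(resid[nonstd])
    warning("skipping non-standard residue(s): ",
            paste(skipped, collapse = ", "))
    atoms <- atoms[!nonstd, , drop = FALSE]
  }

  # altloc: keep the highest-occupancy conformer, first on ties
  alt <- trimws(ifelse(is.na(atoms$alt), "", atoms$alt))
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, trimws(atoms$elety), sep = "|")
    occ <- ifelse(is.na(atoms$o), 1, atoms$o)
    ord <- order(key, -occ, seq_len(nrow(atoms)))
    keep_first <- !duplicated(key[ord])
    atoms <- atoms[sort(ord[keep_first]), , drop = FALSE]
  }

  element <- .element_from_atom(atoms$elety, atoms$elesy)
  mass <- ELEMENT_MASS[element]
  mass[is.na(mass)] <- 0

  out <- data.frame(
    chain = ifelse(is.na(atoms$chain) | atoms$chain == "", "A", atoms$chain),
    resno = atoms$resno,
    resid = toupper(trimws(atoms$resid)),
    elety = trimws(atoms$elety),
    element = element,
    x = atoms$x / 10, y = atoms$y / 10, z = atoms$z / 10,
    mass = unname(mass),
    stringsAsFactors = FALSE)
  if (nrow(out) && any(!is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in input")

  structure(list(atoms = out, water_o = water_o), class = "aa_structure")
}

#' @export
print.aa_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno")]))
  cat("aa_structure:", nrow(x$atoms), "atoms,", nres, "residues,",
      length(unique(x$atoms$chain)), "chain(s),",
      nrow(x$water_o), "water oxygens\n")
  invisible(x)
}

#' Write a coarse-grained structure as a PDB file
#'
#' Beads are written as pseudo-atoms: the bead name goes in the atom-name
#' field (truncated to four characters, `B_ALA` -> `BALA`), the residue name
#' and number are preserved, and optionally the bead charge is placed in the
#' B-factor column.
#'
#' @param cg A `cg_structure`.
#' @param file Output path.
#' @param charge_as_bfactor Put the bead charge in the B-factor column.
#' @return Invisibly, `file`.
#' @export
write_cg_pdb <- function(cg, file, charge_as_bfactor = FALSE) {
  b <- cg$beads
  xyz <- as.vector(t(as.matrix(b[, c("x", "y", "z")]) * 10))  # nm -> A
  atomname <- gsub("_", "", b$bead)
  resid <- ifelse(b$category == "water", "HOH", b$resid)
  bf <- if (charge_as_bfactor) b$charge else rep(0, nrow(b))
  bio3d::write.pdb(file = file, xyz = xyz, type = rep("ATOM", nrow(b)),
                   resno = b$resno, resid = resid,
                   chain = ifelse(is.na(b$chain), "A", b$chain),
                   elety = atomname, o = rep(1, nrow(b)), b = bf)
  invisible(file)
}
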