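#' The 21 coarse-grained bead specifications
#'
#' Returns the bead table of the force field: one backbone bead per
#' small-side-chain residue type, one side-chain bead per large-side-chain
#' residue type (all of which share the uniform `B_GLY` backbone bead), and
#' the five-water solvent bead `W`. Charges are integer elementary charges
#' (`B_ASP` and `S_GLU` carry -1, `S_ARG` and `S_LYS` +1, all other beads are
#' neutral). `c_ii` is the homo-pair Lennard-Jones zero-crossing distance in
#' nm; `eps_ii` the homo-pair well depth in kJ/mol (`NA` for protein beads
#' until a parameter set supplies fitted values; the water bead is fixed at
#' 6 kJ/mol).
#'
#' @return A data frame with one row per bead: `bead`, `category`
#'   (`"backbone"`, `"side"` or `"water"`), `charge`, `c_ii`, `eps_ii`.
#' @examples
#' specs <- bead_specs()
#' subset(specs, charge != 0)
#' @export
bead_specs <- function() {
  beads <- names(LJ_ZERO_CROSSING)
  category <- ifelse(beads == "W", "water",
                     ifelse(startsWith(beads, "B_"), "backbone", "side"))
  charge <- rep(0L, length(beads))
  names(charge) <- beads
  charge[names(BEAD_CHARGE_TABLE)] <- as.integer(BEAD_CHARGE_TABLE)
  eps <- rep(NA_real_, length(beads))
  eps[beads == "W"] <- WATER_EPSILON
  data.frame(bead = beads, category = category,
             charge = unname(charge),
             c_ii = unname(LJ_ZERO_CROSSING),
             eps_ii = eps,
             stringsAsFactors = FALSE)
}

#' Bead name for a residue
#'
#' @param resid Three-letter residue code.
#' @param part `"backbone"` or `"side"`.
#' @return Bead name, e.g. `"B_ALA"`, `"B_GLY"` (backbone of a two-bead
#'   residue) or `"S_ARG"`; `NA` for the side part of a one-bead residue.
#' @export
bead_name <- function(resid, part = c("backbone", "side")) {
  part <- match.arg(part)
  resid <- toupper(resid)
  if (!resid %in% STANDARD_RESIDUES)
    stop("not a standard residue: ", resid)
  if (part == "backbone") {
    if (resid %in% ONE_BEAD_RESIDUES) paste0("B_", resid) else "B_GLY"
  } else {
    if (resid %in% TWO_BEAD_RESIDUES) paste0("S_", resid) else NA_character_
  }
}

#' Formal charge of a bead type
#' @param bead Bead name (e.g. `"S_LYS"`).
#' @return Integer charge in elementary units.
#' @export
bead_charge <- function(bead) {
  out <- integer(length(bead))
  hit <- bead %in% names(BEAD_CHARGE_TABLE)
  out[hit] <- as.integer(BEAD_CHARGE_TABLE[bead[hit]])
  out
}
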