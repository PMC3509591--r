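# Shared fixtures: the packaged parameter set, small peptides, and a PDB
# text snippet exercised by the parser tests.

default_params <- cgff::default_parameters()

deg2rad <- cgff:::deg2rad
rad2deg <- cgff:::rad2deg

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", el = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, el)
}

single_ala_pdb <- c(
  pdb_line(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0),
  pdb_line(2, "CA", "ALA", "A", 1, 1.46, 0.0, 0.0),
  pdb_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0.0),
  pdb_line(4, "O", "ALA", "A", 1, 3.2, 1.5, 0.0),
  pdb_line(5, "CB", "ALA", "A", 1, 2.0, -0.8, 1.2),
  "END")

two_chain_pdb <- c(
  pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
  pdb_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0),
  pdb_line(3, "C", "GLY", "A", 1, 2.0, 1.4, 0),
  pdb_line(4, "N", "ALA", "B", 1, 10, 0, 0),
  pdb_line(5, "CA", "ALA", "B", 1, 11.46, 0, 0),
  pdb_line(6, "C", "ALA", "B", 1, 12.0, 1.4, 0),
  pdb_line(7, "CB", "ALA", "B", 1, 12.0, -0.8, 1.2),
  "END")

altloc_pdb <- c(
  pdb_line(1, "N", "SER", "A", 1, 0, 0, 0),
  pdb_line(2, "CA", "SER", "A", 1, 1.46, 0, 0),
  pdb_line(3, "C", "SER", "A", 1, 2.0, 1.4, 0),
  pdb_line(4, "OG", "SER", "A", 1, 2.2, -1.0, 0.5, occ = 0.4, alt = "A"),
  pdb_line(5, "OG", "SER", "A", 1, 2.3, -1.1, 0.6, occ = 0.6, alt = "B"),
  "END")

# a small mixed-sequence peptide with one- and two-bead residues
mixed_pentapeptide <- function(phi = -57, psi = -47)
  ideal_chain(5, c("ALA", "ARG", "GLU", "LEU", "LYS"), phi = phi,
              psi = psi)

# jittered peptide + parameters for force/energy checks
jittered_system <- function(seed = 42, n = 6) {
  aa <- ideal_chain(n, c("ALA", "ARG", "GLU", "LEU", "LYS", "PHE"),
                    phi = -57, psi = -47)
  cg <- map_structure(aa)
  set.seed(seed)
  cg$beads[, c("x", "y", "z")] <- cg$beads[, c("x", "y", "z")] +
    matrix(rnorm(nrow(cg$beads) * 3, 0, 0.02), ncol = 3)
  list(cg = cg, topo = build_topology(cg))
}

# compact three-helix synthetic fold over the packaged GB1 sequence
# (a synthetic stand-in: the experimental fold is not bundled)
gb1_synthetic_fold <- function() {
  fa <- system.file("extdata", "3gb1_sequence.fasta", package = "cgff")
  seq1 <- readLines(fa)[2]
  res <- cgff:::one_letter_to_three(seq1)
  n <- length(res)
  phi <- rep(-57, n); psi <- rep(-47, n)
  phi[18:20] <- c(-90, 75, -100); psi[18:20] <- c(0, 40, 10)
  phi[38:40] <- c(-90, 75, -100); psi[38:40] <- c(0, 40, 10)
  ideal_chain(n, res, phi = phi, psi = psi)
}

numerical_forces <- function(cg, topo, params, box = NULL, h = 1e-6) {
  p0 <- cg_positions(cg)
  num <- matrix(0, nrow(p0), 3)
  for (i in seq_len(nrow(p0))) for (d in 1:3) {
    cp <- cg; cm <- cg
    cp$beads[i, c("x", "y", "z")[d]] <- p0[i, d] + h
    cm$beads[i, c("x", "y", "z")[d]] <- p0[i, d] - h
    num[i, d] <- -(total_energy(cp, topo, params, box = box,
                                method = "reference")$U_total -
                     total_energy(cm, topo, params, box = box,
                                  method = "reference")$U_total) / (2 * h)
  }
  num
}
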