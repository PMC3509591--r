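# Coarse-grained mapping and topology enumeration.

test_that("PDB parsing keeps atoms, chains and resolves altlocs", {
  aa <- parse_structure(single_ala_pdb)
  expect_s3_class(aa, "aa_structure")
  expect_equal(nrow(unique(aa$atoms[, c("chain", "resno")])), 1L)
  expect_gte(nrow(aa$atoms), 5L)
  expect_true("CA" %in% aa$atoms$elety)
  # coordinates converted A -> nm
  expect_equal(aa$atoms$x[aa$atoms$elety == "CA"], 0.146,
               tolerance = 1e-6)

  two <- parse_structure(two_chain_pdb)
  expect_setequal(unique(two$atoms$chain), c("A", "B"))
  expect_equal(nrow(unique(two$atoms[, c("chain", "resno")])), 2L)

  alt <- parse_structure(altloc_pdb)
  og <- alt$atoms[alt$atoms$elety == "OG", ]
  expect_equal(nrow(og), 1L)           # one conformer kept
  expect_equal(og$x, 0.23, tolerance = 1e-6)  # the higher-occupancy one
})

test_that("residues map to the documented one- or two-bead scheme", {
  aa <- mixed_pentapeptide()
  at <- aa$atoms
  ala <- map_residue(at[at$resno == 1, ])
  expect_equal(ala$bead, "B_ALA")
  expect_equal(ala$charge, 0L)
  expect_equal(nrow(ala), 1L)

  arg <- map_residue(at[at$resno == 2, ])
  expect_equal(arg$bead, c("B_GLY", "S_ARG"))
  expect_equal(arg$charge, c(0L, 1L))
  # backbone bead sits on the Calpha
  ca <- at[at$resno == 2 & at$elety == "CA", c("x", "y", "z")]
  expect_equal(unlist(arg[1, c("x", "y", "z")]), unlist(ca),
               ignore_attr = TRUE)
  # side-chain bead at the heavy-atom geometric center
  side <- at[at$resno == 2 & !(at$elety %in% cgff:::BACKBONE_ATOMS) &
               at$element != "H", c("x", "y", "z")]
  expect_equal(unlist(arg[2, c("x", "y", "z")]), colMeans(side),
               ignore_attr = TRUE)

  asp <- map_residue(transform(at[at$resno == 1, ], resid = "ASP"))
  expect_equal(asp$bead, "B_ASP")
  expect_equal(asp$charge, -1L)
})

test_that("bead specs cover 21 types with the adopted charges and sizes", {
  specs <- bead_specs()
  expect_equal(nrow(specs), 21L)
  expect_equal(sum(specs$category == "water"), 1L)
  charged <- specs$bead[specs$charge != 0]
  expect_setequal(charged, c("B_ASP", "S_GLU", "S_ARG", "S_LYS"))
  expect_equal(specs$charge[specs$bead %in% c("S_ARG", "S_LYS")], c(1L, 1L))
  expect_equal(specs$c_ii[specs$bead == "B_GLY"], 0.40)
  expect_equal(specs$c_ii[specs$bead == "S_TRP"], 0.65)
  expect_equal(specs$c_ii[specs$bead == "W"], 0.51)
  expect_equal(specs$eps_ii[specs$bead == "W"], 6)
})

test_that("bead count identity and total charge hold across sequences", {
  two_bead <- cgff:::TWO_BEAD_RESIDUES
  seqs <- list(rep("GLY", 10),
               c("ALA", "ARG", "ALA"),
               c("ALA", "ARG", "GLU", "ALA"),
               c("TRP", "TYR", "MET", "HIS", "GLN", "ILE", "PHE"))
  for (s in seqs) {
    cg <- map_structure(ideal_chain(max(3, length(s)), s))
    n_res <- max(3, length(s))
    s_full <- rep_len(s, n_res)
    expect_equal(nrow(cg$beads), n_res + sum(s_full %in% two_bead))
    want_q <- sum(s_full %in% c("ARG", "LYS")) -
      sum(s_full %in% c("ASP", "GLU"))
    expect_equal(sum(cg$beads$charge), want_q)
  }
})

test_that("mapping the packaged protein G sequence gives 76 beads", {
  fa <- system.file("extdata", "3gb1_sequence.fasta", package = "cgff")
  seq1 <- readLines(fa)[2]
  cg <- map_structure(ideal_chain(nchar(seq1), seq1))
  expect_equal(nrow(cg$beads), 76L)
})

test_that("topology enumeration matches exhaustive expectations", {
  # ALA-ARG-ALA: 3 bonds (2 B-B + 1 B-S), 3 angles, no dihedrals
  cg <- map_structure(ideal_chain(3, c("ALA", "ARG", "ALA")))
  topo <- build_topology(cg)
  expect_equal(table(topo$bonds$type),
               table(c("B-B", "B-B", "B-S_ARG")))
  expect_equal(sort(topo$angles$type), sort(c("B-B-B", "B-B-S", "S-B-B")))
  expect_equal(nrow(topo$dihedrals), 0L)

  # ALA-ARG-GLU-ALA: 5 bonds, 6 angles, 4 dihedrals, one of each type
  cg4 <- map_structure(ideal_chain(4, c("ALA", "ARG", "GLU", "ALA")))
  t4 <- build_topology(cg4)
  expect_equal(nrow(t4$bonds), 5L)
  expect_equal(nrow(t4$angles), 6L)
  expect_setequal(t4$dihedrals$type,
                  c("S-B-B-S", "S-B-B-B", "B-B-B-S", "B-B-B-B"))
  expect_equal(nrow(t4$dihedrals), 4L)

  # count identities for a longer mixed chain
  s <- c("ALA", "ARG", "GLN", "GLY", "TRP", "SER", "LYS", "VAL")
  cg8 <- map_structure(ideal_chain(8, s))
  t8 <- build_topology(cg8)
  k <- sum(s %in% cgff:::TWO_BEAD_RESIDUES)
  expect_equal(sum(t8$bonds$type == "B-B"), 7L)
  expect_equal(sum(startsWith(t8$bonds$type, "B-S")), k)
  expect_equal(sum(t8$angles$type == "B-B-B"), 6L)
  # every bead in a bond is in the bead list; exclusions cover 1-2 pairs
  expect_true(all(unlist(t8$bonds[, c("i", "j")]) <= nrow(cg8$beads)))
  bonds_sorted <- t(apply(as.matrix(t8$bonds[, c("i", "j")]), 1, sort))
  key <- paste(bonds_sorted[, 1], bonds_sorted[, 2])
  excl_key <- paste(t8$exclusions[, 1], t8$exclusions[, 2])
  expect_true(all(key %in% excl_key))
})

test_that("chain breaks terminate bonded enumeration", {
  cg <- map_structure(ideal_chain(6, "ALA"))
  cg$beads$resno <- c(1:3, 7:9)      # numbering gap after residue 3
  topo <- build_topology(cg)
  expect_equal(nrow(topo$bonds), 4L)  # 2 + 2, no bond across the gap
  expect_equal(nrow(topo$angles), 2L)
})

test_that("single-residue inputs give degenerate but valid topologies", {
  cg <- map_structure(ideal_chain(3, "ALA"))
  cg$beads <- cg$beads[1, , drop = FALSE]
  topo <- build_topology(cg)
  expect_equal(nrow(topo$bonds), 0L)
  expect_equal(nrow(topo$angles), 0L)
})

test_that("water grouping yields 5-molecule beads of 90 amu at centroids", {
  set.seed(11)
  clump <- function(center) sweep(matrix(rnorm(15, 0, 0.05), 5, 3), 2,
                                  center, "+")
  a <- clump(c(0, 0, 0)); b <- clump(c(3, 3, 3))
  wb <- group_waters(rbind(a, b))
  expect_equal(nrow(wb$beads), 2L)
  got <- cg_positions(wb)
  want <- rbind(colMeans(a), colMeans(b))
  got <- got[order(got[, 1]), ]
  expect_equal(got, want[order(want[, 1]), ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(abs(wb$beads$mass - 90.0765) < 1e-6))
  expect_true(all(wb$beads$charge == 0))

  one <- group_waters(clump(c(1, 1, 1)))
  expect_equal(nrow(one$beads), 1L)
  expect_error(group_waters(matrix(0, 3, 3)), "at least")
})

test_that("mapping errors are informative", {
  aa <- parse_structure(single_ala_pdb)
  no_ca <- aa$atoms[aa$atoms$elety != "CA", ]
  expect_error(map_residue(no_ca), "no CA")
  arg_bare <- transform(aa$atoms, resid = "ARG")
  expect_error(map_residue(arg_bare[arg_bare$elety %in%
                                      c("N", "CA", "C", "O"), ]),
               "side-chain")
  hetero <- c(single_ala_pdb[1:5],
              pdb_line(9, "C1", "LIG", "A", 2, 5, 5, 5), "END")
  expect_warning(parse_structure(hetero), "non-standard")
})
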