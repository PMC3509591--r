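# Synthetic-data generators: ideal peptide geometries built by successive
# internal-coordinate placement, Boltzmann-sampled bonded ensembles,
# umbrella windows over a known free-energy profile, and bulk water boxes.
# Everything is deterministic given its seed.

# Standard trans-peptide backbone geometry (nm / degrees).
BB_GEOMETRY <- list(b_n_ca = 0.146, b_ca_c = 0.152, b_c_n = 0.133,
                    a_n_ca_c = 111, a_ca_c_n = 117, a_c_n_ca = 121,
                    omega = 180)

# Heavy side-chain atom names per residue (GLY has none).
SIDECHAIN_ATOMS <- list(
  ALA = "CB", CYS = c("CB", "SG"), SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"), VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), PRO = c("CB", "CG", "CD"),
  ASN = c("CB", "CG", "OD1", "ND2"), ASP = c("CB", "CG", "OD1", "OD2"),
  GLY = character(),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"))

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(code)
}

# place a point at |bond| from c, with bond angle at c and dihedral about
# the b-c axis (NeRF construction); angles in degrees
.nerf_place <- function(a, b, c, bond, angle, dihedral) {
  angle <- deg2rad(angle); dihedral <- deg2rad(dihedral)
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal peptide chain
#'
#' Constructs a poly-peptide backbone with standard trans-peptide geometry
#' (N-Calpha 0.146 nm, Calpha-C 0.152 nm, C-N 0.133 nm; angles
#' 111/117/121 deg; omega 180 deg) at fixed backbone dihedrals, and places
#' schematic side-chain heavy atoms along the Calpha-Cbeta direction — enough
#' to define the side-chain centroid that the coarse-grained mapping needs,
#' with no claim of rotameric realism.
#'
#' @param n_res Number of residues (>= 3), recycled over `sequence`.
#' @param sequence Residue sequence: one-letter string, or character vector
#'   of three-letter codes; recycled to `n_res`.
#' @param phi,psi Backbone dihedrals (degrees); scalars or per-residue
#'   vectors (recycled), so conformational ensembles can be built by
#'   supplying jittered values.
#' @param omega Peptide-bond dihedral (degrees, 180 = trans).
#' @return An `aa_structure`.
#' @examples
#' helix <- ideal_chain(20, "ALA", phi = -57, psi = -47)
#' @export
ideal_chain <- function(n_res, sequence = "ALA", phi = -57, psi = -47,
                        omega = 180) {
  stopifnot(n_res >= 3)
  if (length(sequence) == 1L && !sequence %in% STANDARD_RESIDUES &&
      nchar(sequence) > 3L)
    sequence <- one_letter_to_three(sequence)
  else if (length(sequence) == 1L && nchar(sequence) == 1L)
    sequence <- one_letter_to_three(sequence)
  sequence <- toupper(rep_len(sequence, n_res))
  bad <- setdiff(sequence, STANDARD_RESIDUES)
  if (length(bad)) stop("unknown residue code(s): ",
                        paste(unique(bad), collapse = ", "))
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  g <- BB_GEOMETRY
  # first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  C <- CA + c(-g$b_ca_c * cos(deg2rad(g$a_n_ca_c)),
              g$b_ca_c * sin(deg2rad(g$a_n_ca_c)), 0)
  bb <- vector("list", n_res)
  bb[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_res)[-1]) {
    prev <- bb[[i - 1]]
    Nn <- .nerf_place(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n,
                      psi[i - 1])
    CAn <- .nerf_place(prev$CA, prev$C, Nn, g$b_n_ca, g$a_c_n_ca,
                       omega[i])
    Cn <- .nerf_place(prev$C, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi[i])
    bb[[i]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    res <- sequence[i]
    at <- bb[[i]]
    add <- function(name, pos, el)
      data.frame(chain = "A", resno = i, resid = res, elety = name,
                 element = el, x = pos[1], y = pos[2], z = pos[3],
                 mass = unname(ELEMENT_MASS[el]), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- add("N", at$N, "N")
    rows[[length(rows) + 1L]] <- add("CA", at$CA, "C")
    rows[[length(rows) + 1L]] <- add("C", at$C, "C")
    sc <- SIDECHAIN_ATOMS[[res]]
    if (length(sc)) {
      # Cbeta direction: out of the backbone plane, tetrahedral at Calpha
      b1 <- at$N - at$CA; b1 <- b1 / sqrt(sum(b1^2))
      b2 <- at$C - at$CA; b2 <- b2 / sqrt(sum(b2^2))
      bis <- -(b1 + b2); bis <- bis / sqrt(sum(bis^2))
      perp <- c(b1[2] * b2[3] - b1[3] * b2[2],
                b1[3] * b2[1] - b1[1] * b2[3],
                b1[1] * b2[2] - b1[2] * b2[1])
      perp <- perp / sqrt(sum(perp^2))
      dir <- cos(deg2rad(35)) * bis + sin(deg2rad(35)) * perp
      for (k in seq_along(sc)) {
        pos <- at$CA + (0.153 + 0.125 * (k - 1)) * dir
        el <- substr(sc[k], 1L, 1L)
        rows[[length(rows) + 1L]] <- add(sc[k], pos, el)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  structure(list(atoms = atoms,
                 water_o = matrix(numeric(), ncol = 3,
                                  dimnames = list(NULL, c("x", "y", "z")))),
            class = "aa_structure")
}

#' @rdname ideal_chain
#' @export
ideal_helix <- function(n_res, sequence = "ALA")
  ideal_chain(n_res, sequence, phi = -57, psi = -47)

#' Ideal beta-strand preset
#'
#' Uses the dihedrals of the beta-sheet basin observed in folded proteins
#' (phi = -120 deg, psi = 115 deg), which reproduces the ~120 deg
#' backbone-bead pseudo-angle characteristic of sheet geometry.
#'
#' @inheritParams ideal_chain
#' @export
ideal_strand <- function(n_res, sequence = "ALA")
  ideal_chain(n_res, sequence, phi = -120, psi = 115)

#' Synthetic calibration structure set
#'
#' A balanced ensemble of helical and strand conformers with per-residue
#' dihedral jitter around the two secondary-structure basins, over
#' sequences that cycle through all twenty residue types. This is the
#' structure set the packaged bonded parameters are fitted on; it emulates
#' the spread of internal coordinates in a fold database, not any
#' particular protein.
#'
#' @param n_helix,n_strand Conformers per class; `n_coil` adds loop-like
#'   conformers with broadly distributed dihedrals, which populate the
#'   sparsely visited regions of the profiles (and hence the repulsive
#'   walls of the inverted potentials).
#' @param n_coil Coil conformers.
#' @param n_res Residues per conformer.
#' @param jitter_sd Per-residue phi/psi jitter (degrees).
#' @param seed RNG seed.
#' @return List of `aa_structure` objects.
#' @export
calibration_structures <- function(n_helix = 30L, n_strand = 30L,
                                   n_coil = 20L, n_res = 20L,
                                   jitter_sd = 6, seed = 1L) {
  aas <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  .with_seed(seed, {
    build <- function(k, phi0, psi0) {
      seqres <- aas[(seq_len(n_res) + k) %% length(aas) + 1L]
      ideal_chain(n_res, seqres,
                  phi = phi0 + stats::rnorm(n_res, 0, jitter_sd),
                  psi = psi0 + stats::rnorm(n_res, 0, jitter_sd))
    }
    coil <- function(k) {
      seqres <- aas[(seq_len(n_res) + k) %% length(aas) + 1L]
      ideal_chain(n_res, seqres,
                  phi = stats::runif(n_res, -180, 180),
                  psi = stats::runif(n_res, -180, 180))
    }
    c(lapply(seq_len(n_helix), build, phi0 = -57, psi0 = -47),
      lapply(seq_len(n_strand), build, phi0 = -120, psi0 = 115),
      lapply(seq_len(n_coil), coil))
  })
}

#' Write an all-atom structure as PDB text
#' @param aa An `aa_structure`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_aa_pdb <- function(aa, file) {
  a <- aa$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]) * 10)),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(file)
}

# tabulated-inverse-CDF sampler for densities exp(-U(x)/kBT) on a grid
.boltzmann_sampler <- function(ufun, lo, hi, n, temperature, ngrid = 4096L) {
  x <- seq(lo, hi, length.out = ngrid)
  u <- ufun(x)
  w <- exp(-(u - min(u)) / (KB * temperature))
  cdf <- cumsum(w); cdf <- cdf / cdf[ngrid]
  r <- stats::runif(n)
  stats::approx(cdf, x, xout = r, ties = "ordered", rule = 2)$y
}

#' Sample a bonded coordinate from its Boltzmann distribution
#'
#' Draws i.i.d. samples from `exp(-U(x)/kB T)` by inverse-CDF lookup on a
#' fine grid; used as the synthetic-truth oracle for the parameter-recovery
#' tests of the fitting pipeline.
#'
#' @param param For `kind = "bond"`, a list with `K` (kJ nm^-2 mol^-1) and
#'   `L` (nm); otherwise a [gaussian_sum()].
#' @param kind `"bond"`, `"angle"` or `"torsion"`.
#' @param n Number of samples.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @return Numeric vector of samples (nm for bonds, radians otherwise).
#' @export
sample_bonded_ensemble <- function(param, kind = c("bond", "angle",
                                                   "torsion"),
                                   n, temperature = 300, seed = 1L) {
  kind <- match.arg(kind)
  .with_seed(seed, {
    if (kind == "bond") {
      sigma <- sqrt(KB * temperature / param$K)
      .boltzmann_sampler(function(l) 0.5 * param$K * (l - param$L)^2,
                         max(1e-4, param$L - 6 * sigma),
                         param$L + 6 * sigma, n, temperature)
    } else if (kind == "angle") {
      .boltzmann_sampler(function(x) gaussian_sum_eval(x, param),
                         0, pi, n, temperature)
    } else {
      .boltzmann_sampler(function(x) gaussian_sum_eval(x, param),
                         -pi, pi, n, temperature)
    }
  })
}

#' Generate umbrella-sampling windows over a known profile
#'
#' For each bias center, draws samples from the biased Boltzmann density
#' `exp(-(U(x) + k/2 (x - x0)^2)/kB T)`. The default spacing mimics
#' umbrella windows every 0.05 nm along a pair-distance coordinate.
#'
#' @param true_pmf Function of the coordinate returning energy (kJ/mol), or
#'   a `pmf_curve` (interpolated).
#' @param centers Bias centers.
#' @param stiffness Harmonic bias force constant (kJ mol^-1 per unit^2).
#' @param n_per_window Samples per window.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @return List of windows, each `list(samples, center, stiffness)`, with
#'   `temperature` attached as an attribute.
#' @export
make_umbrella_windows <- function(true_pmf, centers, stiffness = 2000,
                                  n_per_window = 2000, temperature = 300,
                                  seed = 1L) {
  ufun <- if (inherits(true_pmf, "pmf_curve")) {
    function(x) stats::approx(true_pmf$x, true_pmf$U, xout = x,
                              rule = 2)$y
  } else true_pmf
  lo <- min(centers); hi <- max(centers)
  span <- 4 * sqrt(KB * temperature / stiffness)
  windows <- .with_seed(seed, lapply(centers, function(x0) {
    list(samples = .boltzmann_sampler(
           function(x) ufun(x) + 0.5 * stiffness * (x - x0)^2,
           lo - span, hi + span, n_per_window, temperature),
         center = x0, stiffness = stiffness)
  }))
  attr(windows, "temperature") <- temperature
  windows
}

#' Generate a coarse-grained water box
#'
#' Places `n_beads` five-water solvent beads on a jittered cubic lattice
#' inside the box. Errors if the box cannot hold the requested count at a
#' lattice spacing of at least 0.45 nm.
#'
#' @param n_beads Number of water beads.
#' @param box Length-3 numeric box edges (nm).
#' @param seed RNG seed for the jitter.
#' @return A `cg_structure` of water beads.
#' @export
water_box <- function(n_beads, box, seed = 1L) {
  box <- rep_len(as.numeric(box), 3L)
  pts <- .lattice_points(n_beads, box)
  if (is.null(pts))
    stop("box too small for ", n_beads, " water beads at >= 0.45 nm spacing")
  pts <- .with_seed(seed, pts + matrix(stats::runif(3 * nrow(pts),
                                                    -0.03, 0.03),
                                       ncol = 3))
  beads <- data.frame(bead = "W", category = "water", chain = NA_character_,
                      resno = seq_len(nrow(pts)), resid = "HOH",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      mass = WATER_BEAD_MASS, charge = 0L,
                      stringsAsFactors = FALSE)
  .new_cg_structure(beads)
}

# integer lattice dimensions whose product best approaches (and covers)
# n_target at near-bulk spacing; NULL if impossible above min_spacing
.lattice_points <- function(n_target, box, min_spacing = 0.45) {
  a0 <- (1 / 6.69)^(1 / 3)   # bulk bead density 6.69 nm^-3 (1.0 g/cm^3)
  best <- NULL
  for (fx in 0:1) for (fy in 0:1) for (fz in 0:1) {
    dims <- pmax(1L, c(floor(box[1] / a0) + fx, floor(box[2] / a0) + fy,
                       floor(box[3] / a0) + fz))
    if (prod(dims) < n_target) next
    if (any(box / dims < min_spacing)) next
    if (is.null(best) || prod(dims) < prod(best)) best <- dims
  }
  if (is.null(best)) {
    # smallest lattice covering n_target regardless of bulk spacing
    dims <- pmax(1L, ceiling(rep(n_target, 3)^(1 / 3) *
                               box / (prod(box)^(1 / 3))))
    while (prod(dims) < n_target) dims[which.min(box / dims)] <-
        dims[which.min(box / dims)] + 1L
    if (any(box / dims < min_spacing)) return(NULL)
    best <- dims
  }
  sp <- box / best
  g <- expand.grid(x = (seq_len(best[1]) - 0.5) * sp[1],
                   y = (seq_len(best[2]) - 0.5) * sp[2],
                   z = (seq_len(best[3]) - 0.5) * sp[3])
  as.matrix(g[seq_len(n_target), , drop = FALSE])
}
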