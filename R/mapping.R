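# Coarse-grained mapping: one bead per small residue (at the Calpha), a
# uniform B_GLY backbone bead plus a side-chain bead at the side chain's
# heavy-atom geometric center for large residues, and a five-water solvent
# bead.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3",
                    "HA2", "HA3", "OT1", "OT2")

.new_cg_structure <- function(beads) {
  rownames(beads) <- NULL
  structure(list(beads = beads), class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  b <- x$beads
  cat("cg_structure:", nrow(b), "beads (",
      sum(b$category == "backbone"), "backbone,",
      sum(b$category == "side"), "side-chain,",
      sum(b$category == "water"), "water ), total charge",
      sum(b$charge), "e\n")
  invisible(x)
}

#' Bead coordinates of a coarse-grained structure
#' @param cg A `cg_structure`.
#' @return Numeric matrix (n beads x 3), nm.
#' @export
cg_positions <- function(cg) {
  as.matrix(cg$beads[, c("x", "y", "z")])
}

#' Map one residue to its coarse-grained bead(s)
#'
#' Small residues (ALA, ASN, ASP, CYS, GLY, LEU, PRO, SER, THR, VAL) become a
#' single backbone bead `B_<res>` centered on the Calpha. The remaining ten
#' residues become the uniform backbone bead `B_GLY` at the Calpha plus a
#' side-chain bead `S_<res>` at the geometric center of the side chain's
#' heavy atoms. Bead masses are taken from the residue composition
#' (hydrogens included, whether or not they are present in the file): a
#' one-bead residue carries its full in-chain residue mass; for a two-bead
#' residue the backbone bead carries the N-H-CA-HA-C-O moiety mass and the
#' side-chain bead the remainder.
#'
#' @param residue_atoms Data frame of one residue's atoms (rows of an
#'   `aa_structure$atoms`).
#' @return Data frame with one or two bead rows.
#' @export
map_residue <- function(residue_atoms) {
  resid <- unique(residue_atoms$resid)
  stopifnot(length(resid) == 1L)
  if (!resid %in% STANDARD_RESIDUES)
    stop("cannot map non-standard residue ", resid)
  ca <- residue_atoms[trimws(residue_atoms$elety) == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("residue ", resid, " ", unique(residue_atoms$resno),
         " has no CA atom")
  ca <- as.numeric(ca[1L, c("x", "y", "z")])
  chain <- residue_atoms$chain[1L]
  resno <- residue_atoms$resno[1L]

  mk <- function(bead, category, pos, mass) {
    data.frame(bead = bead, category = category, chain = chain,
               resno = resno, resid = resid,
               x = pos[1], y = pos[2], z = pos[3],
               mass = mass, charge = bead_charge(bead),
               stringsAsFactors = FALSE)
  }

  if (resid %in% ONE_BEAD_RESIDUES)
    return(mk(paste0("B_", resid), "backbone", ca, RESIDUE_MASS[[resid]]))

  side <- residue_atoms[!(trimws(residue_atoms$elety) %in% BACKBONE_ATOMS) &
                          residue_atoms$element != "H", , drop = FALSE]
  if (nrow(side) == 0L)
    stop("two-bead residue ", resid, " ", resno,
         " has no side-chain heavy atoms")
  centroid <- colMeans(as.matrix(side[, c("x", "y", "z")]))
  rbind(
    mk("B_GLY", "backbone", ca, BACKBONE_MOIETY_MASS),
    mk(paste0("S_", resid), "side", centroid,
       RESIDUE_MASS[[resid]] - BACKBONE_MOIETY_MASS))
}

#' Map an all-atom structure to a coarse-grained structure
#'
#' Beads appear in residue order, backbone before side chain within a
#' residue, so the bead count is the residue count plus the number of
#' two-bead residues.
#'
#' @param aa An `aa_structure` from [read_structure()] or a generator.
#' @return A `cg_structure` of protein beads (waters are not mapped here;
#'   see [group_waters()] and [solvate()]).
#' @export
map_structure <- function(aa) {
  stopifnot(inherits(aa, "aa_structure"))
  atoms <- aa$atoms
  if (nrow(atoms) == 0L) stop("structure has no protein atoms")
  key <- factor(paste(atoms$chain, atoms$resno, sep = "|"),
                levels = unique(paste(atoms$chain, atoms$resno, sep = "|")))
  beads <- do.call(rbind, lapply(split(atoms, key), map_residue))
  .new_cg_structure(beads)
}

# Residue-level bookkeeping used by the topology builder: one row per
# residue with indices of its backbone/side bead and a chain-break flag.
.residue_table <- function(cg, break_dist = 0.45) {
  b <- cg$beads
  prot <- which(b$category != "water")
  bb <- prot[b$category[prot] == "backbone"]
  if (!length(bb))
    return(data.frame(chain = character(), resno = integer(),
                      bb = integer(), side = integer(),
                      segment = integer(), stringsAsFactors = FALSE))
  rt <- data.frame(chain = b$chain[bb], resno = b$resno[bb], bb = bb,
                   side = NA_integer_, stringsAsFactors = FALSE)
  sc <- prot[b$category[prot] == "side"]
  if (length(sc)) {
    m <- match(paste(b$chain[sc], b$resno[sc]), paste(rt$chain, rt$resno))
    rt$side[m] <- sc
  }
  # split into bonded segments at chain changes, numbering gaps, or long
  # Calpha-Calpha distances (missing loops)
  n <- nrow(rt)
  new_seg <- rep(TRUE, n)
  if (n > 1L) {
    p <- as.matrix(b[rt$bb, c("x", "y", "z")])
    d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
    new_seg[-1] <- rt$chain[-1] != rt$chain[-n] |
      rt$resno[-1] != rt$resno[-n] + 1L | d > break_dist
  }
  rt$segment <- cumsum(new_seg)
  rt
}

#' Enumerate the bonded topology of a coarse-grained structure
#'
#' Bonds are backbone-backbone (`B-B`) between consecutive residues of a
#' chain segment and backbone-side-chain (`B-S_<res>`) within a residue.
#' Angles come in three types (`B-B-B`, `B-B-S`, `S-B-B`) and dihedrals in
#' four (`S-B-B-S`, `S-B-B-B`, `B-B-B-S`, `B-B-B-B`), all defined over the
#' backbone-backbone axis. Chain breaks (chain id change, residue-number
#' gap, or Calpha-Calpha distance above `break_dist`) terminate enumeration.
#' Non-bonded exclusions cover all 1-2 and 1-3 pairs.
#'
#' @param cg A `cg_structure`.
#' @param break_dist Chain-break Calpha-Calpha distance threshold (nm).
#' @return A `cg_topology`: list with data frames `bonds` (`i`, `j`,
#'   `type`), `angles` (`i`, `j`, `k`, `type`), `dihedrals` (`i`, `j`, `k`,
#'   `l`, `type`) and an integer matrix `exclusions` (1-2/1-3 pairs).
#' @export
build_topology <- function(cg, break_dist = 0.45) {
  rt <- .residue_table(cg, break_dist)
  bonds <- angles <- dihedrals <- NULL
  bnd <- function(i, j, type) data.frame(i = i, j = j, type = type,
                                         stringsAsFactors = FALSE)
  for (seg in split(rt, rt$segment)) {
    n <- nrow(seg)
    bb <- seg$bb; sd <- seg$side
    resid <- cg$beads$resid[bb]
    if (n > 1L)
      bonds <- rbind(bonds, bnd(bb[-n], bb[-1], "B-B"))
    has_s <- which(!is.na(sd))
    if (length(has_s))
      bonds <- rbind(bonds, bnd(bb[has_s], sd[has_s],
                                paste0("B-S_", resid[has_s])))
    if (n > 2L)
      angles <- rbind(angles,
                      data.frame(i = bb[1:(n - 2)], j = bb[2:(n - 1)],
                                 k = bb[3:n], type = "B-B-B",
                                 stringsAsFactors = FALSE))
    for (r in has_s) {
      if (r > 1L)       # B(r-1) - B(r) - S(r)
        angles <- rbind(angles, data.frame(i = bb[r - 1], j = bb[r],
                                           k = sd[r], type = "B-B-S",
                                           stringsAsFactors = FALSE))
      if (r < n)        # S(r) - B(r) - B(r+1)
        angles <- rbind(angles, data.frame(i = sd[r], j = bb[r],
                                           k = bb[r + 1], type = "S-B-B",
                                           stringsAsFactors = FALSE))
    }
    if (n > 1L) {
      for (r in seq_len(n - 1L)) {   # axis B(r)-B(r+1)
        starts <- list()
        if (!is.na(sd[r])) starts <- c(starts, list(c(sd[r], "S")))
        if (r > 1L) starts <- c(starts, list(c(bb[r - 1], "B")))
        ends <- list()
        if (!is.na(sd[r + 1])) ends <- c(ends, list(c(sd[r + 1], "S")))
        if (r + 2L <= n) ends <- c(ends, list(c(bb[r + 2], "B")))
        for (s in starts) for (e in ends)
          dihedrals <- rbind(dihedrals,
            data.frame(i = as.integer(s[1]), j = bb[r], k = bb[r + 1],
                       l = as.integer(e[1]),
                       type = paste0(s[2], "-B-B-", e[2]),
                       stringsAsFactors = FALSE))
      }
    }
  }
  empty_b <- data.frame(i = integer(), j = integer(), type = character(),
                        stringsAsFactors = FALSE)
  empty_a <- data.frame(i = integer(), j = integer(), k = integer(),
                        type = character(), stringsAsFactors = FALSE)
  empty_d <- data.frame(i = integer(), j = integer(), k = integer(),
                        l = integer(), type = character(),
                        stringsAsFactors = FALSE)
  topo <- list(bonds = if (is.null(bonds)) empty_b else bonds,
               angles = if (is.null(angles)) empty_a else angles,
               dihedrals = if (is.null(dihedrals)) empty_d else dihedrals)
  topo$exclusions <- .build_exclusions(topo, nrow(cg$beads))
  structure(topo, class = "cg_topology")
}

# 1-2 and 1-3 exclusion pairs from the bond graph.
.build_exclusions <- function(topo, n_beads) {
  b <- topo$bonds
  if (nrow(b) == 0L)
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  adj <- vector("list", n_beads)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  pairs <- rbind(cbind(b$i, b$j),
                 do.call(rbind, lapply(seq_len(n_beads), function(i) {
                   nb <- adj[[i]]
                   if (length(nb) < 2L) return(NULL)
                   t(utils::combn(sort(nb), 2L))
                 })))
  pairs <- t(apply(pairs, 1L, sort))
  pairs <- unique(pairs)
  colnames(pairs) <- c("i", "j")
  pairs
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals,", nrow(x$exclusions),
      "excluded pairs\n")
  invisible(x)
}

#' Group water molecules into five-water solvent beads
#'
#' Clusters water oxygens into groups of exactly five nearest molecules with
#' K-means followed by a greedy capacity-constrained reassignment (points are
#' claimed in order of distance by the nearest centroid with remaining
#' capacity), then places one neutral 90-amu bead at each group centroid. If
#' the molecule count is not divisible by five, the molecules farthest from
#' the overall centroid are trimmed first.
#'
#' @param oxygen_positions Matrix (n x 3) of water oxygen positions, nm.
#' @param group_size Molecules per bead (5).
#' @param seed RNG seed for the K-means initialisation.
#' @return A `cg_structure` of water beads.
#' @export
group_waters <- function(oxygen_positions, group_size = 5L, seed = 1L) {
  x <- as.matrix(oxygen_positions)
  if (nrow(x) < group_size)
    stop("need at least ", group_size, " water molecules, got ", nrow(x))
  extra <- nrow(x) %% group_size
  if (extra > 0L) {
    d <- sqrt(rowSums(sweep(x, 2L, colMeans(x))^2))
    x <- x[order(d)[seq_len(nrow(x) - extra)], , drop = FALSE]
  }
  k <- nrow(x) %/% group_size
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  km <- if (k == 1L) list(centers = matrix(colMeans(x), 1L))
        else stats::kmeans(x, centers = k, nstart = 5L, iter.max = 50L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  centers <- km$centers
  # balanced assignment: nearest centroid with remaining capacity
  d2 <- outer(rowSums(x^2), rep(1, k)) - 2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  assign_to <- integer(nrow(x))
  capacity <- rep(group_size, k)
  ord <- order(apply(d2, 1L, min))
  for (p in ord) {
    choice <- order(d2[p, ])
    g <- choice[which(capacity[choice] > 0L)[1L]]
    assign_to[p] <- g
    capacity[g] <- capacity[g] - 1L
  }
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(x[assign_to == g, , drop = FALSE])))
  beads <- data.frame(bead = "W", category = "water", chain = NA_character_,
                      resno = seq_len(k), resid = "HOH",
                      x = centroids[, 1], y = centroids[, 2],
                      z = centroids[, 3],
                      mass = WATER_BEAD_MASS, charge = 0L,
                      stringsAsFactors = FALSE)
  .new_cg_structure(beads)
}

#' Concatenate coarse-grained structures (e.g. protein + solvent)
#' @param ... `cg_structure` objects.
#' @return A single `cg_structure`.
#' @export
cg_combine <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, TRUE, "cg_structure")))
  .new_cg_structure(do.call(rbind, lapply(parts, `[[`, "beads")))
}

# ---- internal-coordinate measurement over a topology ----------------------

.vec_angle <- function(u, v) {
  cosang <- rowSums(u * v) /
    (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(1, pmax(-1, cosang)))
}

#' Measure bonded internal coordinates
#'
#' Bond lengths (nm), bending angles and torsions (radians) of every bonded
#' term in a topology, evaluated on the bead coordinates.
#'
#' @param cg A `cg_structure`.
#' @param topo Its `cg_topology`.
#' @return List of data frames `bonds` (`value`, `type`), `angles`,
#'   `dihedrals` with values in nm / radians.
#' @export
measure_internal <- function(cg, topo) {
  p <- cg_positions(cg)
  b <- topo$bonds
  bonds <- data.frame(
    value = if (nrow(b)) sqrt(rowSums((p[b$j, , drop = FALSE] -
                                         p[b$i, , drop = FALSE])^2))
            else numeric(),
    type = b$type, stringsAsFactors = FALSE)
  a <- topo$angles
  angles <- data.frame(
    value = if (nrow(a)) .vec_angle(p[a$i, , drop = FALSE] - p[a$j, , drop = FALSE],
                                    p[a$k, , drop = FALSE] - p[a$j, , drop = FALSE])
            else numeric(),
    type = a$type, stringsAsFactors = FALSE)
  d <- topo$dihedrals
  if (nrow(d)) {
    b1 <- p[d$j, , drop = FALSE] - p[d$i, , drop = FALSE]
    b2 <- p[d$k, , drop = FALSE] - p[d$j, , drop = FALSE]
    b3 <- p[d$l, , drop = FALSE] - p[d$k, , drop = FALSE]
    cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                               u[, 3] * v[, 1] - u[, 1] * v[, 3],
                               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    m <- cr(b1, b2); nn <- cr(b2, b3)
    phi <- atan2(rowSums(cr(m, nn) * b2) / sqrt(rowSums(b2^2)),
                 rowSums(m * nn))
    dihedrals <- data.frame(value = phi, type = d$type,
                            stringsAsFactors = FALSE)
  } else {
    dihedrals <- data.frame(value = numeric(), type = character(),
                            stringsAsFactors = FALSE)
  }
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

#' Write a coarse-grained topology as structured text
#'
#' Plain-text sections (`[beads]`, `[bonds]`, `[angles]`, `[dihedrals]`,
#' `[exclusions]`) with one whitespace-separated record per line.
#'
#' @param cg A `cg_structure`; `topo` its topology; `file` output path.
#' @param topo,file See above.
#' @return Invisibly, `file`.
#' @export
write_cg_topology <- function(cg, topo, file) {
  con <- file(file, "w")
  on.exit(close(con))
  b <- cg$beads
  writeLines("; cgff topology (units: nm, amu, e)", con)
  writeLines("[beads]", con)
  writeLines(sprintf("%d %s %s %s %d %.6f %.6f %.6f %.4f %d",
                     seq_len(nrow(b)), b$bead, b$category,
                     ifelse(is.na(b$chain), "-", b$chain), b$resno,
                     b$x, b$y, b$z, b$mass, b$charge), con)
  writeLines("[bonds]", con)
  writeLines(sprintf("%d %d %s", topo$bonds$i, topo$bonds$j,
                     topo$bonds$type), con)
  writeLines("[angles]", con)
  writeLines(sprintf("%d %d %d %s", topo$angles$i, topo$angles$j,
                     topo$angles$k, topo$angles$type), con)
  writeLines("[dihedrals]", con)
  writeLines(sprintf("%d %d %d %d %s", topo$dihedrals$i, topo$dihedrals$j,
                     topo$dihedrals$k, topo$dihedrals$l,
                     topo$dihedrals$type), con)
  writeLines("[exclusions]", con)
  if (nrow(topo$exclusions))
    writeLines(sprintf("%d %d", topo$exclusions[, 1],
                       topo$exclusions[, 2]), con)
  invisible(file)
}
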