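# The potential: U = U_bond + U_angle + U_torsion + U_vdw + U_elec.
# Per-term closed forms live here in R; the C++ engine evaluates the same
# potential for simulation, and the two are held to agree in the tests.

#' Harmonic bond stretching energy
#'
#' `U = 1/2 K (l - L)^2`.
#'
#' @param l Bond length (nm).
#' @param K Force constant (kJ nm^-2 mol^-1).
#' @param L Equilibrium length (nm).
#' @return Energy (kJ/mol).
#' @export
bond_energy <- function(l, K, L) {
  stopifnot(all(l > 0), K > 0, L > 0)
  0.5 * K * (l - L)^2
}

#' Evaluate a Gaussian-sum bonded potential
#'
#' @param x Coordinate (radians); torsions are wrapped by minimum image
#'   relative to each term center.
#' @param g A [gaussian_sum()].
#' @return Energy (kJ/mol), vectorised over `x`.
#' @export
gaussian_sum_eval <- function(x, g) {
  stopifnot(inherits(g, "gaussian_sum"), all(is.finite(x)))
  out <- numeric(length(x))
  for (t in seq_along(g$a)) {
    dx <- x - g$b[t]
    if (g$domain == "torsion") dx <- wrap_pi(dx)
    out <- out + g$a[t] * exp(-(dx / g$c[t])^2)
  }
  out
}

#' Derivative of a Gaussian-sum potential
#' @inheritParams gaussian_sum_eval
#' @return dU/dx (kJ mol^-1 rad^-1).
#' @export
gaussian_sum_deriv <- function(x, g) {
  stopifnot(inherits(g, "gaussian_sum"))
  out <- numeric(length(x))
  for (t in seq_along(g$a)) {
    dx <- x - g$b[t]
    if (g$domain == "torsion") dx <- wrap_pi(dx)
    out <- out - 2 * g$a[t] * dx / g$c[t]^2 * exp(-(dx / g$c[t])^2)
  }
  out
}

#' Lorentz-Berthelot style mixing of Lennard-Jones parameters
#'
#' The zero-crossing mixes geometrically, `c_ij = sqrt(c_ii c_jj)` (the
#' sixth/twelfth-power geometric-mean rule collapses to this), and the well
#' depth as `eps_ij = sqrt(eps_ii eps_jj)`.
#'
#' @param eps_i,c_i,eps_j,c_j Homo-pair well depths (kJ/mol) and
#'   zero-crossings (nm).
#' @return List with `eps` and `c` for the hetero pair.
#' @export
mix_lj <- function(eps_i, c_i, eps_j, c_j) {
  list(eps = sqrt(eps_i * eps_j), c = sqrt(c_i * c_j))
}

#' Lennard-Jones 12-6 pair energy
#'
#' `U = 4 eps ((c/r)^12 - (c/r)^6)`: zero at `r = c`, minimum `-eps` at
#' `r = 2^(1/6) c`.
#'
#' @param r Distance (nm); must exceed the 0.01 nm overlap floor.
#' @param eps Well depth (kJ/mol).
#' @param c Zero-crossing distance (nm).
#' @param cutoff Optional cutoff (nm): beyond it the energy is 0 and inside
#'   it the potential is shifted so it vanishes continuously at the cutoff.
#' @return Energy (kJ/mol), vectorised over `r`.
#' @export
vdw_pair_energy <- function(r, eps, c, cutoff = NULL) {
  if (any(r < 0.01))
    stop("bead overlap: pair distance below 0.01 nm")
  s6 <- (c / r)^6
  u <- 4 * eps * (s6^2 - s6)
  if (!is.null(cutoff)) {
    sc6 <- (c / cutoff)^6
    u <- ifelse(r < cutoff, u - 4 * eps * (sc6^2 - sc6), 0)
  }
  u
}

#' Coulomb pair energy between point charges
#'
#' `U = Q_i Q_j / (4 pi eps0 eps_r r)` with the prefactor 138.935
#' kJ mol^-1 nm e^-2.
#'
#' @param r Distance (nm).
#' @param qi,qj Charges (e).
#' @param er Relative dielectric constant.
#' @param cutoff Optional shift-to-zero cutoff (nm).
#' @return Energy (kJ/mol).
#' @export
coulomb_pair_energy <- function(r, qi, qj, er = 1, cutoff = NULL) {
  if (any(r < 0.01))
    stop("bead overlap: pair distance below 0.01 nm")
  u <- KE_COULOMB * qi * qj / (er * r)
  if (!is.null(cutoff))
    u <- ifelse(r < cutoff, u - KE_COULOMB * qi * qj / (er * cutoff), 0)
  u
}

# parameter lookups with errors that name the missing type -----------------

.bond_params <- function(types, params) {
  miss <- setdiff(unique(types), names(params$bonds))
  if (length(miss))
    stop("no bond parameters for type(s): ", paste(miss, collapse = ", "))
  K <- vapply(params$bonds, `[[`, 0, "K")[types]
  L <- vapply(params$bonds, `[[`, 0, "L")[types]
  list(K = unname(K), L = unname(L))
}

.angle_params <- function(types, params) {
  keys <- .resolve_angle_key(types)
  miss <- setdiff(unique(keys), names(params$angles))
  if (length(miss))
    stop("no angle parameters for type(s): ", paste(miss, collapse = ", "))
  keys
}

.torsion_params <- function(types, params) {
  miss <- setdiff(unique(types), names(params$torsions))
  if (length(miss))
    stop("no torsion parameters for type(s): ", paste(miss, collapse = ", "))
  types
}

.lj_index <- function(beads, params) {
  idx <- match(beads, params$lj$bead)
  if (anyNA(idx))
    stop("no LJ parameters for bead type(s): ",
         paste(unique(beads[is.na(idx)]), collapse = ", "))
  idx
}

.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
}

# Pure-R reference evaluation of the full potential (O(N^2) pairs); the
# C++ engine is validated against this in the tests.
.total_energy_r <- function(cg, topo, params, box = NULL) {
  p <- cg_positions(cg)
  n <- nrow(p)
  meas <- measure_internal(cg, topo)

  u_bond <- if (nrow(topo$bonds)) {
    bp <- .bond_params(topo$bonds$type, params)
    sum(0.5 * bp$K * (meas$bonds$value - bp$L)^2)
  } else 0

  u_angle <- 0
  if (nrow(topo$angles)) {
    keys <- .angle_params(topo$angles$type, params)
    for (k in unique(keys))
      u_angle <- u_angle +
        sum(gaussian_sum_eval(meas$angles$value[keys == k],
                              params$angles[[k]]))
  }
  u_tors <- 0
  if (nrow(topo$dihedrals)) {
    keys <- .torsion_params(topo$dihedrals$type, params)
    for (k in unique(keys))
      u_tors <- u_tors +
        sum(gaussian_sum_eval(meas$dihedrals$value[keys == k],
                              params$torsions[[k]]))
  }

  u_vdw <- u_elec <- 0
  if (n > 1L) {
    idx <- .lj_index(cg$beads$bead, params)
    eps <- params$lj$eps[idx]; cc <- params$lj$c[idx]
    q <- cg$beads$charge
    excl <- topo$exclusions
    excl_key <- if (nrow(excl)) excl[, 1] * (n + 1) + excl[, 2] else integer()
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      key <- i * (n + 1) + j
      j <- j[!(key %in% excl_key)]
      if (!length(j)) next
      d <- .min_image(p[j, , drop = FALSE] -
                        matrix(p[i, ], length(j), 3, byrow = TRUE), box)
      r <- sqrt(rowSums(d^2))
      inside <- r < params$cutoff
      if (!any(inside)) next
      r <- r[inside]; jj <- j[inside]
      pm <- mix_lj(eps[i], cc[i], eps[jj], cc[jj])
      u_vdw <- u_vdw + sum(vdw_pair_energy(r, pm$eps, pm$c,
                                           cutoff = params$cutoff))
      qq <- q[i] * q[jj]
      nz <- qq != 0
      if (any(nz))
        u_elec <- u_elec + sum(coulomb_pair_energy(r[nz], 1, qq[nz],
                                                   er = params$er,
                                                   cutoff = params$cutoff))
    }
  }
  breakdown(u_bond, u_angle, u_tors, u_vdw, u_elec)
}

breakdown <- function(u_bond, u_angle, u_tors, u_vdw, u_elec) {
  structure(list(U_bond = u_bond, U_angle = u_angle, U_torsion = u_tors,
                 U_vdw = u_vdw, U_elec = u_elec,
                 U_total = u_bond + u_angle + u_tors + u_vdw + u_elec),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "U_bond %.4f  U_angle %.4f  U_torsion %.4f  U_vdw %.4f  U_elec %.4f  U_total %.4f kJ/mol\n",
    x$U_bond, x$U_angle, x$U_torsion, x$U_vdw, x$U_elec, x$U_total))
  invisible(x)
}

#' Total coarse-grained potential energy
#'
#' Bonded terms are summed over the topology lists; non-bonded terms over
#' all non-excluded pairs within the cutoff (minimum-image convention when a
#' periodic box is given), with both the Lennard-Jones and Coulomb
#' potentials shifted to zero at the cutoff.
#'
#' @param cg A `cg_structure`.
#' @param topo Its `cg_topology`.
#' @param params A `cg_parameters` object.
#' @param box Periodic box edge lengths (length-3 numeric, nm), or `NULL`
#'   for an isolated system.
#' @param method `"engine"` (compiled, cell lists) or `"reference"` (plain R,
#'   all pairs; used as the independent check in the tests).
#' @return An `energy_breakdown` with components and their sum (kJ/mol).
#' @export
total_energy <- function(cg, topo, params, box = NULL,
                         method = c("engine", "reference")) {
  method <- match.arg(method)
  if (method == "reference") return(.total_energy_r(cg, topo, params, box))
  ef <- .engine_eval(cg_positions(cg), cg, topo, params, box)
  breakdown(ef$U_bond, ef$U_angle, ef$U_torsion, ef$U_vdw, ef$U_elec)
}

#' Analytic forces of the coarse-grained potential
#'
#' `F = -grad U`, evaluated by the compiled engine.
#'
#' @inheritParams total_energy
#' @return Matrix (n beads x 3) of forces (kJ mol^-1 nm^-1).
#' @export
forces <- function(cg, topo, params, box = NULL) {
  .engine_eval(cg_positions(cg), cg, topo, params, box)$forces
}

# Flatten structure/topology/parameters into the arrays the C++ engine
# consumes. Gaussian parameters are concatenated with per-type offsets.
.engine_input <- function(cg, topo, params) {
  n <- nrow(cg$beads)
  lj_idx <- .lj_index(cg$beads$bead, params)
  nt <- nrow(params$lj)
  epsm <- sqrt(outer(params$lj$eps, params$lj$eps))
  cm <- sqrt(outer(params$lj$c, params$lj$c))

  bp <- if (nrow(topo$bonds)) .bond_params(topo$bonds$type, params)
        else list(K = numeric(), L = numeric())

  pack_gauss <- function(lst, keys) {
    uk <- names(lst)
    offs <- c(0L, cumsum(vapply(lst, function(g) length(g$a), 0L)))
    list(type = match(keys, uk) - 1L,
         offsets = as.integer(offs),
         a = unlist(lapply(lst, `[[`, "a"), use.names = FALSE),
         b = unlist(lapply(lst, `[[`, "b"), use.names = FALSE),
         c = unlist(lapply(lst, `[[`, "c"), use.names = FALSE))
  }
  ga <- pack_gauss(params$angles,
                   if (nrow(topo$angles)) .angle_params(topo$angles$type, params)
                   else character())
  gt <- pack_gauss(params$torsions,
                   if (nrow(topo$dihedrals)) .torsion_params(topo$dihedrals$type, params)
                   else character())

  excl <- topo$exclusions
  # CSR adjacency of excluded partners per bead (0-based for C++)
  adj <- vector("list", n)
  if (nrow(excl)) {
    for (r in seq_len(nrow(excl))) {
      i <- excl[r, 1]; j <- excl[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  excl_ptr <- c(0L, cumsum(vapply(adj, length, 0L)))
  excl_idx <- unlist(adj, use.names = FALSE)
  excl_idx <- if (is.null(excl_idx)) integer() else excl_idx - 1L

  list(n = n,
       type = lj_idx - 1L,
       mass = cg$beads$mass,
       charge = as.numeric(cg$beads$charge),
       eps_table = epsm, c_table = cm,
       bond_i = topo$bonds$i - 1L, bond_j = topo$bonds$j - 1L,
       bond_K = bp$K, bond_L = bp$L,
       ang_i = topo$angles$i - 1L, ang_j = topo$angles$j - 1L,
       ang_k = topo$angles$k - 1L, ang_type = ga$type,
       ga_off = ga$offsets, ga_a = ga$a, ga_b = ga$b, ga_c = ga$c,
       dih_i = topo$dihedrals$i - 1L, dih_j = topo$dihedrals$j - 1L,
       dih_k = topo$dihedrals$k - 1L, dih_l = topo$dihedrals$l - 1L,
       dih_type = gt$type,
       gt_off = gt$offsets, gt_a = gt$a, gt_b = gt$b, gt_c = gt$c,
       excl_ptr = as.integer(excl_ptr), excl_idx = as.integer(excl_idx),
       er = params$er, cutoff = params$cutoff)
}

.engine_eval <- function(pos, cg, topo, params, box = NULL) {
  inp <- .engine_input(cg, topo, params)
  boxv <- if (is.null(box)) numeric() else as.numeric(box)
  res <- cg_engine_eval(pos, inp, boxv)
  res
}
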