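# Minimal CG-MD: solvation, steepest-descent minimization, and
# velocity-Verlet dynamics with Berendsen temperature coupling, all driven
# by the compiled engine.

#' Simulation configuration
#'
#' @param dt Time step (ps). The coarse resolution supports 0.016 ps (16 fs).
#' @param temperature Target temperature (K).
#' @param tau_t Berendsen coupling time (ps); `0` disables the thermostat
#'   (NVE).
#' @param cutoff Non-bonded cutoff (nm); overrides the parameter set's.
#' @param n_steps Number of MD steps.
#' @param stride Output stride (steps between recorded frames).
#' @param seed RNG seed for the Maxwell-Boltzmann initial velocities.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.016, temperature = 300, tau_t = 1,
                       cutoff = 1.2, n_steps = 1000L, stride = 10L,
                       seed = 1L) {
  stopifnot(dt > 0, temperature > 0, cutoff > 0, n_steps >= 1,
            stride >= 1)
  structure(list(dt = dt, temperature = temperature, tau_t = tau_t,
                 cutoff = cutoff, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#' @param file Path to a YAML file whose keys match [sim_config()]'s
#'   arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(sim_config, vals[intersect(names(vals),
                                     names(formals(sim_config)))])
}

#' Solvate a coarse-grained protein in CG water
#'
#' Centers the protein in a rectangular periodic box whose edges clear the
#' molecule by `margin` on every side, fills the box with five-water beads
#' on a jittered lattice at the bulk bead density (6.69 beads nm^-3, i.e.
#' five-water beads at 1.0 g/cm^3), and removes waters within `overlap` of
#' any protein bead.
#'
#' @param cg A protein `cg_structure`.
#' @param margin Box clearance around the protein (nm).
#' @param cutoff Non-bonded cutoff the box must accommodate (nm): each box
#'   edge must reach twice the cutoff.
#' @param overlap Water-removal distance from protein beads (nm).
#' @param seed RNG seed for the lattice jitter.
#' @return A list (`cg_system`): `structure` (protein + water
#'   `cg_structure`), `box` (length-3, nm), `n_water`.
#' @export
solvate <- function(cg, margin = 1, cutoff = 1.2, overlap = 0.45,
                    seed = 1L) {
  p <- cg_positions(cg)
  extent <- apply(p, 2L, function(v) diff(range(v)))
  box <- extent + 2 * margin
  if (any(box < 2 * cutoff))
    stop("margin too small: box edge ", format(min(box), digits = 3),
         " nm is below twice the cutoff (", 2 * cutoff, " nm)")
  # center the protein
  shift <- box / 2 - (apply(p, 2L, min) + extent / 2)
  beads <- cg$beads
  beads[, c("x", "y", "z")] <- sweep(p, 2L, shift, "+")
  prot <- .new_cg_structure(beads)

  n_target <- round(6.69 * prod(box))
  wb <- water_box(n_target, box, seed = seed)
  wp <- cg_positions(wb)
  pp <- cg_positions(prot)
  keep <- rep(TRUE, nrow(wp))
  for (i in seq_len(nrow(pp))) {
    d2 <- (wp[, 1] - pp[i, 1])^2 + (wp[, 2] - pp[i, 2])^2 +
      (wp[, 3] - pp[i, 3])^2
    keep <- keep & d2 > overlap^2
  }
  wb$beads <- wb$beads[keep, , drop = FALSE]
  wb$beads$resno <- seq_len(nrow(wb$beads))
  sys <- cg_combine(prot, wb)
  structure(list(structure = sys, box = box, n_water = nrow(wb$beads)),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat("cg_system:", nrow(x$structure$beads), "beads (", x$n_water,
      "water ) in box", paste(format(x$box, digits = 4), collapse = " x "),
      "nm\n")
  invisible(x)
}

#' Steepest-descent energy minimization
#'
#' Adaptive-step steepest descent: a trial move along the force direction is
#' accepted only if the energy does not increase (so the energy trace is
#' monotone non-increasing), growing the step on success and halving it on
#' rejection. Stops when the largest force component falls below `f_tol`.
#'
#' @param cg A `cg_structure`.
#' @param topo Its `cg_topology`.
#' @param params A `cg_parameters`.
#' @param box Periodic box (length-3 nm) or `NULL`.
#' @param max_steps Step cap.
#' @param f_tol Force tolerance (kJ mol^-1 nm^-1).
#' @return The `cg_structure` with minimized positions; attributes
#'   `energy`, `steps`, `converged`.
#' @export
minimize <- function(cg, topo, params, box = NULL, max_steps = 1000L,
                     f_tol = 10) {
  inp <- .engine_input(cg, topo, params)
  boxv <- if (is.null(box)) numeric() else as.numeric(box)
  res <- cg_engine_minimize(cg_positions(cg), inp, boxv,
                            as.integer(max_steps), f_tol, 0.005)
  out <- cg
  out$beads[, c("x", "y", "z")] <- res$pos
  attr(out, "energy") <- res$energy
  attr(out, "steps") <- res$steps
  attr(out, "converged") <- res$converged
  out
}

#' Run coarse-grained molecular dynamics
#'
#' Velocity-Verlet integration with minimum-image periodic boundaries, a
#' Verlet pair list (0.3 nm skin, rebuilt when any bead moves more than half
#' the skin) and Berendsen velocity rescaling toward the target temperature.
#' Initial velocities are Maxwell-Boltzmann at the target temperature with
#' the configured seed, with the center-of-mass momentum removed.
#'
#' @param cg A `cg_structure` (protein, solvated system, or water box).
#' @param topo Its `cg_topology`.
#' @param params A `cg_parameters`.
#' @param config A [sim_config()].
#' @param box Periodic box (length-3 nm) or `NULL` for vacuum.
#' @param velocities Optional starting velocities (n x 3, nm/ps); default
#'   Maxwell-Boltzmann.
#' @return A `cg_trajectory`: `positions` array (frames x beads x 3),
#'   `times` (ps), `energies` data frame (per recorded frame), `box`,
#'   `beads` (bead table), and final `state` (positions, velocities).
#' @export
run_md <- function(cg, topo, params, config, box = NULL,
                   velocities = NULL) {
  stopifnot(inherits(config, "sim_config"))
  params$cutoff <- config$cutoff
  if (!is.null(box) && any(box < 2 * params$cutoff))
    stop("box must be at least twice the cutoff in every dimension")
  inp <- .engine_input(cg, topo, params)
  n <- nrow(cg$beads)
  if (is.null(velocities)) {
    velocities <- .with_seed(config$seed,
      matrix(stats::rnorm(3 * n), n, 3) *
        sqrt(KB * config$temperature / cg$beads$mass))
    # remove center-of-mass drift, then rescale to the exact target
    m <- cg$beads$mass
    velocities <- sweep(velocities, 2L, colSums(velocities * m) / sum(m))
    ke <- 0.5 * sum(m * rowSums(velocities^2))
    Tin <- 2 * ke / ((3 * n - 3) * KB)
    velocities <- velocities * sqrt(config$temperature / Tin)
  }
  boxv <- if (is.null(box)) numeric() else as.numeric(box)
  res <- cg_engine_run(cg_positions(cg), velocities, inp, boxv,
                       config$dt, config$n_steps, config$temperature,
                       config$tau_t, config$stride)
  en <- data.frame(time = res$times, epot = res$epot, ekin = res$ekin,
                   etot = res$epot + res$ekin,
                   temperature = res$temperature,
                   U_bond = res$components[, 1],
                   U_angle = res$components[, 2],
                   U_torsion = res$components[, 3],
                   U_vdw = res$components[, 4],
                   U_elec = res$components[, 5])
  structure(list(positions = res$trajectory, times = res$times,
                 energies = en, box = box, beads = cg$beads,
                 state = list(pos = res$pos, vel = res$vel)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat("cg_trajectory:", d[1], "frames,", d[2], "beads,",
      format(max(x$times), digits = 5), "ps\n")
  invisible(x)
}

#' Wrap positions into the periodic box
#' @param pos n x 3 matrix (nm).
#' @param box Length-3 box edges (nm).
#' @return Wrapped matrix.
#' @export
wrap_positions <- function(pos, box) {
  sweep(pos, 2L, box, function(p, b) p - b * floor(p / b))
}

#' Write a trajectory energy log as TSV
#' @param traj A `cg_trajectory`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_energy_log <- function(traj, file) {
  utils::write.table(traj$energies, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Write a trajectory as multi-model PDB
#' @param traj A `cg_trajectory`.
#' @param file Output path.
#' @param stride Keep every `stride`-th recorded frame.
#' @return Invisibly, `file`.
#' @export
write_trajectory_pdb <- function(traj, file, stride = 1L) {
  frames <- seq(1L, dim(traj$positions)[1], by = stride)
  con <- file(file, "w")
  on.exit(close(con))
  b <- traj$beads
  name <- substr(gsub("_", "", b$bead), 1, 4)
  for (fr in frames) {
    writeLines(sprintf("MODEL     %4d", fr), con)
    p <- traj$positions[fr, , , drop = TRUE] * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(b)) %% 100000L, name,
      ifelse(b$category == "water", "HOH", b$resid),
      ifelse(is.na(b$chain), "A", b$chain),
      b$resno %% 10000L, p[, 1], p[, 2], p[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
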