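# Solvation, minimization and the MD integrator.

test_that("solvation fills the box at bulk density and clears the
           protein", {
  # bulk density check: 181 beads fit a 3 nm cube at 6.69 nm^-3
  wb <- water_box(round(6.69 * 27), c(3, 3, 3), seed = 1)
  expect_equal(nrow(wb$beads), 181L)
  expect_lt(abs(nrow(wb$beads) / 27 - 6.69) / 6.69, 0.05)

  cg <- map_structure(ideal_helix(12, "ALA"))
  sys <- solvate(cg, margin = 1, seed = 2)
  expect_true(all(sys$box >= 2 * 1.2))
  wp <- cg_positions(sys$structure)[sys$structure$beads$category ==
                                      "water", , drop = FALSE]
  pp <- cg_positions(sys$structure)[sys$structure$beads$category !=
                                      "water", , drop = FALSE]
  dmin <- min(as.matrix(stats::dist(rbind(pp, wp)))[
    seq_len(nrow(pp)), nrow(pp) + seq_len(nrow(wp))])
  expect_gt(dmin, 0.45)
  # water count tracks the accessible volume at bulk density within 15%
  vol <- prod(sys$box)
  expect_lt(abs(sys$n_water - 6.69 * vol) / (6.69 * vol), 0.15)
  expect_error(solvate(cg, margin = 0.2), "margin")
})

test_that("minimization is monotone and finds simple minima", {
  # two water beads at the LJ minimum distance stay put
  wb <- water_box(5, c(3, 3, 3), seed = 3)
  wb$beads <- wb$beads[1:2, ]
  wb$beads$x <- c(0.5, 0.5 + 2^(1 / 6) * 0.51)
  wb$beads$y <- 0.5; wb$beads$z <- 0.5
  topo <- build_topology(wb)
  m <- minimize(wb, topo, default_params, max_steps = 200, f_tol = 1e-4)
  expect_equal(cg_positions(m), cg_positions(wb), tolerance = 1e-6)

  # a stretched B-B bond relaxes to 0.38 nm
  cg <- map_structure(ideal_chain(3, "GLY"))
  cg$beads <- cg$beads[1:2, ]
  cg$beads$x <- c(0, 0.40); cg$beads[, c("y", "z")] <- 0
  t2 <- build_topology(cg)
  m2 <- minimize(cg, t2, default_params, max_steps = 500, f_tol = 1e-3)
  d <- dist(cg_positions(m2))[1]
  expect_equal(as.numeric(d), 0.38, tolerance = 1e-4)
  expect_lte(attr(m2, "energy"),
             total_energy(cg, t2, default_params)$U_total)
})

test_that("a zero-velocity, zero-force start stays static", {
  wb <- water_box(8, c(4, 4, 4), seed = 4)
  # spread beads far apart so no interaction survives the cutoff
  wb$beads[, c("x", "y", "z")] <- as.matrix(
    expand.grid(c(0.5, 2.5), c(0.5, 2.5), c(0.5, 2.5)))
  topo <- build_topology(wb)
  cfg <- sim_config(dt = 0.016, tau_t = 0, n_steps = 100, stride = 10)
  tr <- run_md(wb, topo, default_params, cfg, box = c(4, 4, 4),
               velocities = matrix(0, 8, 3))
  expect_equal(tr$state$pos, cg_positions(wb), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("NVE energy drift is small and shrinks as O(dt^2)", {
  wb <- water_box(64, c(3.6, 3.6, 3.6), seed = 5)
  topo <- build_topology(wb)
  drift_at <- function(dt, nsteps) {
    cfg <- sim_config(dt = dt, temperature = 300, tau_t = 0,
                      n_steps = nsteps, stride = nsteps / 10, seed = 6)
    e <- run_md(wb, topo, default_params, cfg,
                box = c(3.6, 3.6, 3.6))$energies
    abs(e$etot[nrow(e)] - e$etot[1]) / mean(e$ekin)
  }
  d1 <- drift_at(0.002, 10000)
  expect_lt(d1, 0.02)
  d2 <- drift_at(0.001, 20000)    # same simulated time, halved step
  expect_lt(d2, d1 / 3)
})

test_that("the thermostat holds 300 K and preserves zero momentum", {
  wb <- water_box(64, c(3.6, 3.6, 3.6), seed = 7)
  topo <- build_topology(wb)
  cfg <- sim_config(dt = 0.016, temperature = 300, tau_t = 1,
                    n_steps = 20000, stride = 20, seed = 8)
  tr <- run_md(wb, topo, default_params, cfg, box = c(3.6, 3.6, 3.6))
  temps <- tr$energies$temperature
  expect_lt(abs(mean(temps[-(1:100)]) - 300), 10)
  mom <- colSums(tr$state$vel * wb$beads$mass)
  expect_lt(max(abs(mom)) / sum(wb$beads$mass), 1e-10)
})

test_that("blow-ups are reported with the step number", {
  wb <- water_box(5, c(3, 3, 3), seed = 9)
  topo <- build_topology(wb)
  cfg <- sim_config(dt = 50, tau_t = 0, n_steps = 1000, stride = 100,
                    seed = 10)  # absurd step size
  expect_error(run_md(wb, topo, default_params, cfg, box = c(3, 3, 3)),
               "step|overlap")
})

test_that("configs round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("dt: 0.016", "temperature: 310", "n_steps: 50",
               "stride: 5", "seed: 3"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$temperature, 310)
  expect_equal(cfg$n_steps, 50L)
})

test_that("trajectory writers produce readable output", {
  wb <- water_box(10, c(3, 3, 3), seed = 11)
  topo <- build_topology(wb)
  cfg <- sim_config(dt = 0.008, n_steps = 50, stride = 10, seed = 12)
  tr <- run_md(wb, topo, default_params, cfg, box = c(3, 3, 3))
  pdbf <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, pdbf)
  expect_equal(sum(grepl("^MODEL", readLines(pdbf))),
               dim(tr$positions)[1])
  tsvf <- tempfile(fileext = ".tsv")
  write_energy_log(tr, tsvf)
  log <- utils::read.table(tsvf, header = TRUE, sep = "\t")
  expect_equal(nrow(log), dim(tr$positions)[1])
  expect_true(all(c("epot", "ekin", "temperature") %in% names(log)))
})
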