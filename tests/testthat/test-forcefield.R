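# Potential functions, parameter mixing, total energy and analytic forces.

test_that("harmonic bond energy follows the closed form", {
  expect_equal(bond_energy(0.38, 1e5, 0.38), 0)
  expect_equal(bond_energy(0.39, 1e5, 0.38), 5.0)
  expect_equal(bond_energy(0.37, 1e5, 0.38), bond_energy(0.39, 1e5, 0.38))
})

test_that("Gaussian sums evaluate, differentiate and wrap correctly", {
  g <- gaussian_sum(1, 0, 1, domain = "angle")
  expect_equal(gaussian_sum_eval(0, g), 1)
  expect_equal(gaussian_sum_eval(1, g), exp(-1))
  # torsion periodicity: center near +175 deg seen from -175 deg
  gt <- gaussian_sum(2, 175 * pi / 180, 0.3, domain = "torsion")
  expect_equal(gaussian_sum_eval(-175 * pi / 180, gt),
               gaussian_sum_eval(185 * pi / 180, gt))
  # analytic derivative vs numeric
  x <- seq(-3, 3, by = 0.37)
  h <- 1e-6
  num <- (gaussian_sum_eval(x + h, g) - gaussian_sum_eval(x - h, g)) /
    (2 * h)
  expect_equal(gaussian_sum_deriv(x, g), num, tolerance = 1e-7)
})

test_that("mixing rule is geometric, symmetric and idempotent", {
  m <- mix_lj(3, 0.40, 5, 0.65)
  expect_equal(m$c, sqrt(0.40 * 0.65))
  expect_equal(m$c, 0.5099, tolerance = 1e-4)
  expect_equal(m$eps, sqrt(15))
  expect_equal(mix_lj(3, 0.4, 5, 0.65), mix_lj(5, 0.65, 3, 0.4))
  same <- mix_lj(4, 0.5, 4, 0.5)
  expect_equal(same, list(eps = 4, c = 0.5))
})

test_that("12-6 potential has the documented zero and minimum", {
  # water pair: zero at 0.51, minimum -6 at 2^(1/6) 0.51
  expect_equal(vdw_pair_energy(0.51, 6, 0.51), 0)
  expect_equal(vdw_pair_energy(2^(1 / 6) * 0.51, 6, 0.51), -6)
  # alanine backbone pair crosses zero at 0.50
  lj <- default_params$lj
  ala <- lj[lj$bead == "B_ALA", ]
  expect_equal(vdw_pair_energy(0.50, ala$eps, ala$c), 0)
  # minimum equals -eps at 2^(1/6) c for every mixed pair in the table
  for (i in seq_len(nrow(lj))) for (j in seq_len(nrow(lj))) {
    m <- mix_lj(lj$eps[i], lj$c[i], lj$eps[j], lj$c[j])
    expect_equal(vdw_pair_energy(2^(1 / 6) * m$c, m$eps, m$c), -m$eps,
                 tolerance = 1e-12)
  }
  expect_error(vdw_pair_energy(0.005, 6, 0.51), "overlap")
})

test_that("Coulomb term uses the 138.935 prefactor and its symmetries", {
  expect_equal(coulomb_pair_energy(1, 1, 1), 138.935)
  expect_equal(coulomb_pair_energy(0.7, 0, 3), 0)
  expect_equal(coulomb_pair_energy(0.7, -1, 1),
               -coulomb_pair_energy(0.7, 1, 1))
})

test_that("total energy composes the five terms and matches the engine", {
  js <- jittered_system()
  for (box in list(NULL, c(4, 4, 4))) {
    e_ref <- total_energy(js$cg, js$topo, default_params, box = box,
                          method = "reference")
    e_cpp <- total_energy(js$cg, js$topo, default_params, box = box,
                          method = "engine")
    expect_equal(e_ref$U_total,
                 e_ref$U_bond + e_ref$U_angle + e_ref$U_torsion +
                   e_ref$U_vdw + e_ref$U_elec)
    for (k in c("U_bond", "U_angle", "U_torsion", "U_vdw", "U_elec"))
      expect_equal(e_cpp[[k]], e_ref[[k]], tolerance = 1e-10)
  }
})

test_that("isolated far-apart neutral beads have zero energy", {
  cg <- map_structure(ideal_chain(3, "ALA"))
  cg$beads <- cg$beads[c(1, 2), ]
  cg$beads$x <- c(0, 5)  # beyond cutoff
  cg$beads[, c("y", "z")] <- 0
  topo <- build_topology(cg)
  topo$bonds <- topo$bonds[0, ]       # no bonded terms
  topo$exclusions <- cgff:::.build_exclusions(topo, 2L)
  e <- total_energy(cg, topo, default_params, method = "reference")
  expect_equal(e$U_total, 0)
})

test_that("two like charges in range give the pair Coulomb energy", {
  cg <- map_structure(ideal_chain(3, "ALA"))
  cg$beads <- cg$beads[c(1, 2), ]
  cg$beads$bead <- "S_LYS"; cg$beads$charge <- 1L
  cg$beads$x <- c(0, 0.9); cg$beads[, c("y", "z")] <- 0
  topo <- build_topology(cg)
  topo$bonds <- topo$bonds[0, ]
  topo$exclusions <- cgff:::.build_exclusions(topo, 2L)
  e <- total_energy(cg, topo, default_params, method = "reference")
  expect_gt(e$U_elec, 0)
  expect_equal(e$U_elec,
               coulomb_pair_energy(0.9, 1, 1, cutoff = default_params$cutoff))
})

test_that("analytic forces match central differences to 1e-5 relative", {
  js <- jittered_system(seed = 9, n = 6)
  for (box in list(NULL, c(4, 4, 4))) {
    f <- forces(js$cg, js$topo, default_params, box = box)
    num <- numerical_forces(js$cg, js$topo, default_params, box = box)
    expect_lt(max(abs(f - num)) / max(abs(f)), 1e-5)
    # Newton's third law: an isolated system feels no net force
    expect_lt(max(abs(colSums(f))), 1e-8)
  }
})

test_that("bond at equilibrium exerts no force", {
  cg <- map_structure(ideal_chain(3, "GLY"))
  cg$beads <- cg$beads[1:2, ]
  cg$beads$x <- c(0, 0.38); cg$beads[, c("y", "z")] <- 0
  topo <- build_topology(cg)
  f <- forces(cg, topo, default_params)
  # the only interaction is the (excluded-from-nonbonded) B-B bond
  expect_lt(max(abs(f)), 1e-9)
})

test_that("energy is invariant under rigid motions of isolated systems", {
  js <- jittered_system(seed = 3)
  e0 <- total_energy(js$cg, js$topo, default_params,
                     method = "engine")$U_total
  set.seed(21)
  for (rep in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    cg2 <- js$cg
    cg2$beads[, c("x", "y", "z")] <-
      cg_positions(js$cg) %*% t(R) +
      matrix(rnorm(3), nrow(js$cg$beads), 3, byrow = TRUE)
    e1 <- total_energy(cg2, js$topo, default_params,
                       method = "engine")$U_total
    expect_lt(abs(e1 - e0), 1e-8)
  }
})

test_that("missing parameters raise errors naming the offending type", {
  js <- jittered_system()
  p2 <- default_params
  p2$bonds[["B-S_ARG"]] <- NULL
  expect_error(total_energy(js$cg, js$topo, p2, method = "reference"),
               "B-S_ARG")
  p3 <- default_params
  p3$lj <- p3$lj[p3$lj$bead != "S_PHE", ]
  expect_error(total_energy(js$cg, js$topo, p3, method = "reference"),
               "S_PHE")
})

test_that("parameter sets round-trip through JSON exactly", {
  f <- tempfile(fileext = ".json")
  write_parameters(default_params, f)
  back <- read_parameters(f)
  expect_equal(back, default_params)
})

test_that("exported tables are self-consistent and periodic", {
  dir <- tempfile()
  files <- export_tables(default_params, dir, spacing = 1)
  ang <- utils::read.table(file.path(dir, "table_BBB_angle.txt"),
                           header = FALSE, skip = 1)
  g <- default_params$angles[["B-B-B"]]
  expect_equal(ang$V2, gaussian_sum_eval(ang$V1 * pi / 180, g),
               tolerance = 1e-8)
  # central-difference derivative of the energy column matches column 3
  # to O(spacing^2): quartering the spacing cuts the error ~16-fold
  fd_err <- function(spacing) {
    d2 <- tempfile()
    export_tables(default_params, d2, spacing = spacing)
    tb <- utils::read.table(file.path(d2, "table_BBB_angle.txt"),
                            header = FALSE, skip = 1)
    n <- nrow(tb)
    dnum <- (tb$V2[-(1:2)] - tb$V2[1:(n - 2)]) / (2 * spacing)
    max(abs(tb$V3[2:(n - 1)] + dnum))
  }
  e1 <- fd_err(1)
  expect_lt(e1, 0.5)
  expect_lt(fd_err(0.25), e1 / 8)
  tor <- utils::read.table(file.path(dir, "table_BBBB_torsion.txt"),
                           header = FALSE, skip = 1)
  expect_equal(tor$V2[1], tor$V2[nrow(tor)], tolerance = 1e-10)
})
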