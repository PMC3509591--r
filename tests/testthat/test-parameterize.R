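# Boltzmann inversion, fitting, profile merging and WHAM.

kB <- 0.0083145

test_that("histograms conserve counts and structure statistics land where
           the geometry puts them", {
  helix <- ideal_chain(20, "ALA", phi = -57, psi = -47)
  h <- collect_internal_coordinates(list(helix), "bond")
  expect_named(h, "B-B")
  expect_equal(sum(h[["B-B"]]$counts), 19L)      # n-1 bonds measured
  centers <- (h[["B-B"]]$edges[-1] +
                h[["B-B"]]$edges[-length(h[["B-B"]]$edges)]) / 2
  peak <- centers[which.max(h[["B-B"]]$counts)]
  expect_lt(abs(peak - 0.38), 0.01               # narrow band at 3.8 A
  )
  expect_warning(
    collect_internal_coordinates(list(helix), "bond", complete = TRUE),
    "B-S_ARG")
  expect_error(collect_internal_coordinates(list(), "bond"), "empty")
})

test_that("Boltzmann inversion matches the closed form", {
  # uniform histogram -> flat zero curve
  hu <- cg_histogram(rep(seq(0.3, 0.5, by = 0.005) + 0.0025, each = 4),
                     "bond")
  pu <- boltzmann_invert(hu, 300)
  expect_true(all(abs(pu$U[pu$defined]) < 1e-12))
  # counts 2:1 -> dU = kB 300 ln 2 = 1.729
  h2 <- cg_histogram(c(rep(0.3525, 2), 0.3575), "bond")
  p2 <- boltzmann_invert(h2, 300)
  expect_equal(diff(range(p2$U[p2$defined])), kB * 300 * log(2),
               tolerance = 1e-10)
  expect_equal(kB * 300 * log(2), 1.729, tolerance = 1e-3)
  empty <- cg_histogram(numeric(0), "angle")
  expect_error(boltzmann_invert(empty), "empty")
})

test_that("inversion of Boltzmann-distributed samples recovers the
           potential", {
  g <- gaussian_sum(c(8, 6), c(1.4, 2.2), c(0.25, 0.3), domain = "angle")
  x <- sample_bonded_ensemble(g, "angle", n = 2e5, temperature = 300,
                              seed = 5)
  pmf <- boltzmann_invert(cg_histogram(x, "angle"), 300)
  truth <- gaussian_sum_eval(pmf$x, g)
  keep <- pmf$defined & truth - min(truth) < 6   # well-sampled region
  resid <- (pmf$U - (truth - min(truth)))[keep]
  resid <- resid - mean(resid)                   # additive constant free
  expect_lt(sqrt(mean(resid^2)), 0.25)
})

test_that("harmonic fits recover bond parameters", {
  # exact round trip
  l <- seq(0.25, 0.35, by = 0.001)
  pmf <- pmf_curve(l, 0.5 * 5000 * (l - 0.301)^2, 300)
  fit <- fit_harmonic(pmf)
  expect_equal(fit$K, 5000, tolerance = 1e-6)
  expect_equal(fit$L, 0.301, tolerance = 1e-8)
  # from sampled ensemble at the GLN side-chain bond geometry
  s <- sample_bonded_ensemble(list(K = 5000, L = 0.301), "bond", 2e5,
                              300, seed = 6)
  fit2 <- fit_harmonic(boltzmann_invert(cg_histogram(s, "bond"), 300))
  expect_equal(fit2$L, 0.301, tolerance = 0.01)
  expect_equal(fit2$K, 5000, tolerance = 0.01 * 5000)
  # uniform noise barely moves the minimum
  set.seed(7)
  noisy <- pmf_curve(l, 0.5 * 5000 * (l - 0.301)^2 +
                       runif(length(l), 0, 0.1), 300)
  expect_lt(abs(fit_harmonic(noisy)$L - 0.301), 0.005)  # < bin width
  mono <- pmf_curve(l, 50 * l, 300)
  expect_error(fit_harmonic(mono), "monotone|minimum")
})

test_that("Gaussian-sum fits recover synthetic profiles", {
  # single-term round trip to < 0.1%
  x <- seq(0, pi, length.out = 200)
  g1 <- gaussian_sum(5, 1.7, 0.4, domain = "angle")
  fit <- fit_gaussian_sum(pmf_curve(x, gaussian_sum_eval(x, g1) + 5, 300),
                          "angle")
  expect_equal(fit$n_terms, 1L)
  expect_equal(sort(fit$param$b), 1.7, tolerance = 1e-3)
  expect_equal(abs(fit$param$a), 5, tolerance = 5e-3)

  # two-well angle profile (helix/sheet-like): fitted minima within 2 deg
  # of the generating profile's minima
  g2 <- gaussian_sum(c(6, -4, -3.5), c(deg2rad(105), pi / 2, 2 * pi / 3),
                     c(0.2, 0.12, 0.12), domain = "angle")
  samp <- sample_bonded_ensemble(g2, "angle", 3e5, 300, seed = 8)
  pmf <- boltzmann_invert(cg_histogram(samp, "angle"), 300)
  fit2 <- fit_gaussian_sum(pmf, "angle")
  grid <- seq(deg2rad(60), deg2rad(150), length.out = 4000)
  u <- gaussian_sum_eval(grid, fit2$param)
  ut <- gaussian_sum_eval(grid, g2)
  lo <- grid < deg2rad(105)
  for (side in list(lo, !lo)) {
    m_fit <- grid[side][which.min(u[side])]
    m_true <- grid[side][which.min(ut[side])]
    expect_lt(abs(rad2deg(m_fit - m_true)), 2)
  }

  # torsion fit is unchanged when the profile is shifted by +360 deg
  xt <- seq(-pi, pi, length.out = 180)
  gt <- gaussian_sum(c(4, 2), c(0.4, -2.4), c(0.5, 0.4),
                     domain = "torsion")
  p1 <- pmf_curve(xt, gaussian_sum_eval(xt, gt), 300)
  p2 <- pmf_curve(xt + 2 * pi, gaussian_sum_eval(xt, gt), 300)
  f1 <- fit_gaussian_sum(p1, "torsion")
  f2 <- fit_gaussian_sum(p2, "torsion")
  xx <- seq(-pi, pi, length.out = 73)
  expect_equal(gaussian_sum_eval(xx, f1$param),
               gaussian_sum_eval(xx, f2$param), tolerance = 1e-4)
})

test_that("profile merging averages, smooths and re-zeroes", {
  x <- seq(0, pi, length.out = 90)
  base <- pmf_curve(x, 3 * (1 - cos(2 * x)), 300)
  # duplicating the input does not change the merge result
  expect_equal(merge_profiles(list(base, base))$U,
               merge_profiles(list(base))$U, tolerance = 1e-12)
  expect_equal(merge_profiles(list(base, base), window = 1L)$U, base$U,
               tolerance = 1e-10)
  shifted <- pmf_curve(x, 3 * (1 - cos(2 * x)) + 2, 300)
  m <- merge_profiles(list(base, shifted), window = 1L)
  expect_equal(m$U, base$U, tolerance = 1e-10)  # offset washes out
  # averaging beats any single noisy copy
  set.seed(9)
  noisy <- lapply(1:10, function(i)
    pmf_curve(x, 3 * (1 - cos(2 * x)) + rnorm(length(x), 0, 0.4), 300))
  merged <- merge_profiles(noisy)
  l2 <- function(p) sqrt(mean((p$U - base$U)^2))
  expect_lt(l2(merged), min(vapply(noisy, l2, 0)))
  expect_error(merge_profiles(list()), "empty")
})

test_that("long-range well-depth fits are domain-restricted as designed", {
  r <- seq(0.42, 1.5, by = 0.005)
  u_exact <- vdw_pair_energy(r, 6, 0.51)
  fit <- fit_lj_depth(pmf_curve(r, u_exact, 300), 0.51)
  expect_equal(fit$eps, 6, tolerance = 1e-6)
  # truncating to r >= c changes nothing (that is the fit domain anyway)
  rt <- r[r >= 0.51]
  fit2 <- fit_lj_depth(pmf_curve(rt, vdw_pair_energy(rt, 6, 0.51), 300),
                       0.51)
  expect_equal(fit2$eps, fit$eps, tolerance = 1e-6)
  # perturbing the short-range barrier leaves eps untouched
  u_pert <- u_exact + 3 * exp(-((r - 0.45) / 0.02)^2)
  fit3 <- fit_lj_depth(pmf_curve(r, u_pert, 300), 0.51)
  expect_equal(fit3$eps, fit$eps, tolerance = 1e-3)
  # purely repulsive profile is rejected
  expect_error(fit_lj_depth(pmf_curve(r, (0.51 / r)^12, 300), 0.51),
               "repulsive")
})

test_that("packaged well depths reproduce the packaged synthetic PMFs", {
  for (bd in c("B_ALA", "S_TRP", "B_GLY")) {
    f <- system.file("extdata", "pmf_synthetic", paste0(bd, ".txt"),
                     package = "cgff")
    cii <- bead_specs()$c_ii[bead_specs()$bead == bd]
    fit <- fit_lj_depth(read_pmf(f), cii)
    packaged <- default_params$lj$eps[default_params$lj$bead == bd]
    expect_equal(fit$eps, packaged, tolerance = 1e-8)
  }
})

test_that("WHAM reduces to inversion for a single unbiased window", {
  set.seed(10)
  samp <- rnorm(5e4, 0.6, 0.04)
  win <- list(list(samples = samp, center = 0.6, stiffness = 0))
  p_wham <- wham(win, 300, bin_width = 0.005)
  p_inv <- boltzmann_invert(cg_histogram(samp, "pair"), 300)
  common <- intersect(round(p_wham$x, 6), round(p_inv$x, 6))
  iw <- match(common, round(p_wham$x, 6))
  ii <- match(common, round(p_inv$x, 6))
  expect_equal(p_wham$U[iw], p_inv$U[ii], tolerance = 1e-8)
})

test_that("WHAM reconstructs a synthetic double-well profile", {
  truth <- function(x) 8 * (1 - exp(-((x - 0.5) / 0.08)^2)) *
    (1 - exp(-((x - 0.9) / 0.08)^2))
  centers <- seq(0.35, 1.05, by = 0.05)    # umbrella spacing 0.05 nm
  wins <- make_umbrella_windows(truth, centers, stiffness = 1500,
                                n_per_window = 4000, temperature = 300,
                                seed = 11)
  pmf <- wham(wins, 300, bin_width = 0.01)
  keep <- pmf$defined & pmf$x > 0.4 & pmf$x < 1.0
  tu <- truth(pmf$x[keep]); tu <- tu - min(tu)
  expect_lt(sqrt(mean((pmf$U[keep] - tu)^2)), 0.2)
  expect_false(attr(pmf, "flagged"))
  # window order is immaterial
  pmf2 <- wham(rev(wins), 300, bin_width = 0.01)
  expect_equal(pmf2$U, pmf$U, tolerance = 1e-9)
})

test_that("non-overlapping windows are flagged", {
  w <- make_umbrella_windows(function(x) 0 * x, c(0.3, 1.2),
                             stiffness = 50000, n_per_window = 500,
                             temperature = 300, seed = 12)
  expect_warning(res <- wham(w, 300, bin_width = 0.005), "overlap")
  expect_true(attr(res, "flagged"))
})
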