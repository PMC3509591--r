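# Statistical parameterization: internal-coordinate histograms over a
# structure set, Boltzmann inversion to potentials of mean force, harmonic /
# Gaussian-sum / Lennard-Jones-depth fitting, profile merging, and WHAM for
# umbrella-sampling windows.

U_CAP <- 25          # kJ/mol cap for empty bins (~10 kBT at 300 K)
HARMONIC_FIT_MAX <- 5    # kJ/mol, harmonic-region fit window
GAUSS_RMS_TOL <- 0.5     # kJ/mol, Gaussian-sum model-selection threshold

# default bin widths: bonds / pair distances 0.005 nm, angles 2 deg,
# torsions 5 deg
.bin_width <- function(kind) {
  switch(kind, bond = 0.005, pair = 0.005,
         angle = deg2rad(2), torsion = deg2rad(5))
}

#' Construct a histogram of an internal coordinate
#' @param values Observed coordinate values (nm or radians).
#' @param kind `"bond"`, `"angle"`, `"torsion"` or `"pair"`.
#' @param width Bin width; defaults to the kind's convention (0.005 nm for
#'   distances, 2 deg for angles, 5 deg for torsions).
#' @return A `cg_histogram`: list with `edges`, `counts`, `n_ref`, `kind`.
#' @export
cg_histogram <- function(values, kind = c("bond", "angle", "torsion",
                                          "pair"),
                         width = NULL) {
  kind <- match.arg(kind)
  if (is.null(width)) width <- .bin_width(kind)
  if (kind == "torsion") {
    edges <- seq(-pi, pi, by = width)
    if (edges[length(edges)] < pi) edges <- c(edges, pi)
  } else if (kind == "angle") {
    edges <- seq(0, pi + width, by = width)
  } else {
    lo <- floor(min(values) / width) * width
    hi <- ceiling(max(values) / width) * width
    edges <- seq(lo, hi + width / 2, by = width)
  }
  counts <- as.integer(table(cut(values, edges, include.lowest = TRUE,
                                 labels = FALSE)) [
    as.character(seq_len(length(edges) - 1L))])
  counts[is.na(counts)] <- 0L
  structure(list(edges = edges, counts = counts, n_ref = length(values),
                 kind = kind), class = "cg_histogram")
}

#' @export
print.cg_histogram <- function(x, ...) {
  cat("cg_histogram (", x$kind, "): ", length(x$counts), " bins, n_ref ",
      x$n_ref, "\n", sep = "")
  invisible(x)
}

#' Internal-coordinate statistics over a structure set
#'
#' Maps every structure to coarse-grained beads, enumerates the bonded
#' topology and histograms each term by type. `kind = "pair"` instead
#' histograms non-bonded (beyond 1-2/1-3 exclusions) same-type bead-pair
#' distances up to `r_max`, the statistic behind the Lennard-Jones
#' zero-crossing distances.
#'
#' @param structures List of `aa_structure` objects.
#' @param kind `"bond"`, `"angle"`, `"torsion"` or `"pair"`.
#' @param r_max Pair-distance cap (nm) for `kind = "pair"`.
#' @param complete Warn about bead/term types absent from the set.
#' @return Named list of `cg_histogram`, one per observed term type.
#' @export
collect_internal_coordinates <- function(structures,
                                         kind = c("bond", "angle",
                                                  "torsion", "pair"),
                                         r_max = 1.5, complete = FALSE) {
  kind <- match.arg(kind)
  if (!length(structures)) stop("empty structure set")
  vals <- list()
  push <- function(type, v) {
    vals[[type]] <<- c(vals[[type]], v)
  }
  for (aa in structures) {
    cg <- map_structure(aa)
    topo <- build_topology(cg)
    if (kind == "pair") {
      p <- cg_positions(cg)
      n <- nrow(p)
      excl_key <- if (nrow(topo$exclusions))
        topo$exclusions[, 1] * (n + 1) + topo$exclusions[, 2] else integer()
      beads <- cg$beads$bead
      for (bt in unique(beads)) {
        idx <- which(beads == bt)
        if (length(idx) < 2L) next
        cmb <- utils::combn(idx, 2L)
        key <- cmb[1, ] * (n + 1) + cmb[2, ]
        keep <- !(key %in% excl_key)
        if (!any(keep)) next
        d <- sqrt(rowSums((p[cmb[1, keep], , drop = FALSE] -
                             p[cmb[2, keep], , drop = FALSE])^2))
        d <- d[d <= r_max]
        if (length(d)) push(bt, d)
      }
    } else {
      meas <- measure_internal(cg, topo)
      tab <- switch(kind, bond = meas$bonds, angle = meas$angles,
                    torsion = meas$dihedrals)
      for (tt in unique(tab$type)) push(tt, tab$value[tab$type == tt])
    }
  }
  if (complete) {
    expected <- switch(kind,
      bond = c("B-B", paste0("B-S_", TWO_BEAD_RESIDUES)),
      angle = c("B-B-B", "B-B-S", "S-B-B"),
      torsion = c("S-B-B-S", "S-B-B-B", "B-B-B-S", "B-B-B-B"),
      pair = names(LJ_ZERO_CROSSING)[names(LJ_ZERO_CROSSING) != "W"])
    missing <- setdiff(expected, names(vals))
    if (length(missing))
      warning("no observations for type(s): ",
              paste(missing, collapse = ", "))
  }
  hkind <- if (kind == "pair") "pair" else kind
  lapply(vals, cg_histogram, kind = hkind)
}

#' Construct a potential-of-mean-force curve
#' @param x Coordinate grid.
#' @param U Energies (kJ/mol); shifted so the defined minimum is 0.
#' @param temperature Kelvin.
#' @param defined Logical mask of bins with data (default all).
#' @return A `pmf_curve`.
#' @export
pmf_curve <- function(x, U, temperature = 300, defined = NULL) {
  if (is.null(defined)) defined <- is.finite(U)
  if (!any(defined)) stop("PMF has no defined bins")
  U <- U - min(U[defined])
  U[!defined] <- U_CAP
  structure(list(x = as.numeric(x), U = as.numeric(U),
                 temperature = temperature, defined = defined),
            class = "pmf_curve")
}

#' @export
print.pmf_curve <- function(x, ...) {
  cat("pmf_curve:", length(x$x), "points on [",
      format(min(x$x), digits = 4), ",", format(max(x$x), digits = 4),
      "], T =", x$temperature, "K,", sum(x$defined), "defined\n")
  invisible(x)
}

#' Boltzmann inversion of a histogram
#'
#' `U_i = -kB T log(n_i / n_ref)` on occupied bins, shifted so the minimum
#' is zero. Empty bins are marked undefined and capped at 25 kJ/mol
#' (about 10 kB T at 300 K); they are excluded from all fits.
#'
#' @param h A `cg_histogram`.
#' @param temperature Kelvin.
#' @return A `pmf_curve` on the bin centers.
#' @export
boltzmann_invert <- function(h, temperature = 300) {
  stopifnot(inherits(h, "cg_histogram"))
  if (h$n_ref == 0L || !any(h$counts > 0)) stop("all histogram bins empty")
  centers <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
  p <- h$counts / h$n_ref
  U <- ifelse(h$counts > 0, -KB * temperature * log(p), NA_real_)
  pmf_curve(centers, U, temperature, defined = h$counts > 0)
}

#' Fit a harmonic bond potential to a PMF
#'
#' Least-squares quadratic fit `U = K/2 (l - L)^2` restricted to the
#' harmonic region (defined bins with `U <= 5` kJ/mol around the minimum).
#'
#' @param pmf A `pmf_curve` over a bond length.
#' @return List with `K`, `L`, `rms` (kJ/mol, fit domain only) and
#'   `domain` (range of lengths used).
#' @export
fit_harmonic <- function(pmf) {
  ok <- pmf$defined & pmf$U <= HARMONIC_FIT_MAX
  x <- pmf$x[ok]; u <- pmf$U[ok]
  if (length(x) < 3L) stop("too few points in the harmonic region")
  imin <- which.min(pmf$U[pmf$defined])
  xmin_all <- pmf$x[pmf$defined][imin]
  if (xmin_all <= min(x) || xmin_all >= max(x))
    stop("PMF is monotone on the fit domain; no interior minimum")
  fit <- stats::lm(u ~ x + I(x^2))
  a2 <- stats::coef(fit)[["I(x^2)"]]
  a1 <- stats::coef(fit)[["x"]]
  if (a2 <= 0) stop("PMF is not convex on the fit domain")
  K <- 2 * a2
  L <- -a1 / (2 * a2)
  list(K = K, L = L, rms = sqrt(mean(stats::resid(fit)^2)),
       domain = range(x))
}

# local maxima of a series (interior strict peaks), returned by height
.find_peaks <- function(x, u) {
  n <- length(u)
  if (n < 3L) return(integer())
  idx <- which(u[2:(n - 1)] >= u[1:(n - 2)] & u[2:(n - 1)] >= u[3:n]) + 1L
  idx[order(u[idx], decreasing = TRUE)]
}

#' Fit a Gaussian-sum bonded potential to a PMF
#'
#' Nonlinear least squares of `sum_i a_i exp(-((x-b_i)/c_i)^2)` with a
#' greedy residual-peak initialisation plus a fixed set of seeded restart
#' perturbations (the fit is deterministic). The number of terms is the
#' smallest
#' `N <= n_max` whose RMS residual on the defined bins falls below
#' 0.5 kJ/mol, else `n_max`. Torsion fits wrap the deviation from each
#' center by minimum image, so the result is periodic.
#'
#' @param pmf A `pmf_curve` over an angle or torsion (radians).
#' @param domain `"angle"` or `"torsion"`.
#' @param n_max Maximum number of Gaussian terms.
#' @param wall_bins Also anchor the fit on the capped undefined bins (at
#'   25 kJ/mol, half weight). A region never visited in the statistics is
#'   at least ~10 kBT uphill, and without these anchors the Gaussian terms
#'   decay to zero there, leaving spurious flat minima outside the sampled
#'   range. Reported residuals always refer to the defined bins only.
#' @return List with `param` (a [gaussian_sum()]), `rms` (defined bins),
#'   `n_terms`, `converged`.
#' @export
fit_gaussian_sum <- function(pmf, domain = c("angle", "torsion"),
                             n_max = 6L, wall_bins = TRUE) {
  domain <- match.arg(domain)
  ok <- pmf$defined
  x <- pmf$x[ok]; u <- pmf$U[ok]
  if (length(x) < 5L) stop("too few defined bins for a Gaussian-sum fit")
  n_data <- length(x)
  wts <- rep(1, n_data)
  if (wall_bins && any(!ok)) {
    x <- c(x, pmf$x[!ok])
    u <- c(u, rep(U_CAP, sum(!ok)))
    wts <- c(wts, rep(0.5, sum(!ok)))
  }
  ord <- order(x)
  x <- x[ord]; u <- u[ord]; wts <- wts[ord]
  data_idx <- which(wts == 1)
  wrap <- domain == "torsion"
  # last parameter is a free constant offset: the profile's energy origin
  # (minimum shifted to zero) is arbitrary and not representable by a sum
  # of decaying Gaussians; the offset is dropped from the returned
  # potential, which only changes it by an additive constant
  model <- function(par, xx) {
    nterm <- (length(par) - 1L) / 3
    a <- par[seq_len(nterm)]
    b <- par[nterm + seq_len(nterm)]
    cc <- par[2 * nterm + seq_len(nterm)]
    out <- rep(par[length(par)], length(xx))
    for (t in seq_len(nterm)) {
      dx <- xx - b[t]
      if (wrap) dx <- wrap_pi(dx)
      out <- out + a[t] * exp(-(dx / cc[t])^2)
    }
    out
  }
  span <- diff(range(x))
  # greedy residual-peak initialisation: each successive term takes the
  # largest remaining |residual| with a half-maximum width estimate
  greedy_init <- function(nterm) {
    resid <- u
    pars <- matrix(0, nterm, 3)
    for (t in seq_len(nterm)) {
      m <- which.max(abs(resid))
      a0 <- resid[m]; b0 <- x[m]
      th <- abs(a0) / 2
      lo <- m
      while (lo > 1L && abs(resid[lo - 1L]) > th &&
               sign(resid[lo - 1L]) == sign(a0)) lo <- lo - 1L
      hi <- m
      while (hi < length(x) && abs(resid[hi + 1L]) > th &&
               sign(resid[hi + 1L]) == sign(a0)) hi <- hi + 1L
      c0 <- max((x[hi] - x[lo]) / 1.665, span / 100)
      pars[t, ] <- c(a0, b0, c0)
      dx <- x - b0
      if (wrap) dx <- wrap_pi(dx)
      resid <- resid - a0 * exp(-(dx / c0)^2)
    }
    pars
  }
  best <- NULL
  n_restarts <- 5L
  for (nterm in seq_len(n_max)) {
    p0 <- greedy_init(nterm)
    lower <- c(rep(-2 * max(u) - 1, nterm),
               rep(min(x) - span / 2, nterm), rep(span / 200, nterm),
               -2 * max(u) - 1)
    upper <- c(rep(2 * max(u) + 10, nterm),
               rep(max(x) + span / 2, nterm), rep(2 * span, nterm),
               2 * max(u) + 10)
    # greedy start plus seeded random perturbations of it
    starts <- .with_seed(7451 + nterm, c(
      list(c(p0[, 1], p0[, 2], p0[, 3], 0)),
      lapply(seq_len(n_restarts), function(r)
        c(p0[, 1] * (1 + stats::rnorm(nterm, 0, 0.3)),
          p0[, 2] + stats::rnorm(nterm, 0, span / 12),
          p0[, 3] * exp(stats::rnorm(nterm, 0, 0.4)),
          stats::rnorm(1, 0, 1)))))
    rms_n <- Inf; par_n <- NULL
    for (par0 in starts) {
      par0 <- pmin(pmax(par0, lower), upper)
      res <- try(minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper,
        fn = function(p) sqrt(wts) * (model(p, x) - u),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        silent = TRUE)
      if (inherits(res, "try-error")) next
      rms <- sqrt(mean((model(res$par, x) - u)[data_idx]^2))
      if (rms < rms_n) { rms_n <- rms; par_n <- res$par }
    }
    if (is.null(par_n)) next
    if (is.null(best) || rms_n < best$rms) {
      a <- par_n[seq_len(nterm)]
      b <- par_n[nterm + seq_len(nterm)]
      cc <- par_n[2 * nterm + seq_len(nterm)]
      # constant offset par_n[3*nterm+1] dropped (additive only)
      if (wrap) b <- wrap_pi(b)
      best <- list(param = gaussian_sum(a, b, cc, domain = domain),
                   rms = rms_n, n_terms = nterm,
                   converged = rms_n < GAUSS_RMS_TOL)
    }
    if (rms_n < GAUSS_RMS_TOL) break
  }
  if (is.null(best)) stop("Gaussian-sum fit failed at every N")
  if (!best$converged)
    warning("Gaussian-sum fit did not reach RMS < ", GAUSS_RMS_TOL,
            " kJ/mol (best RMS ", format(best$rms, digits = 3), ")")
  best
}

#' Merge several PMF profiles into one
#'
#' Resamples every profile onto a common grid, takes the pointwise mean
#' over defined bins, applies a 3-bin moving-average smoothing, and
#' re-shifts the minimum to zero.
#'
#' @param profiles List of `pmf_curve` objects.
#' @param window Moving-average window (bins, odd).
#' @return A `pmf_curve`.
#' @export
merge_profiles <- function(profiles, window = 3L) {
  if (!length(profiles)) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, TRUE, "pmf_curve")))
  grid <- profiles[[1L]]$x
  acc <- matrix(NA_real_, length(grid), length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    acc[, i] <- stats::approx(p$x[p$defined], p$U[p$defined], xout = grid,
                              rule = 1)$y
  }
  m <- rowMeans(acc, na.rm = TRUE)
  defined <- rowSums(!is.na(acc)) > 0
  m[!defined] <- NA_real_
  if (window > 1L) {
    k <- rep(1 / window, window)
    sm <- stats::filter(m, k, sides = 2)
    m <- ifelse(is.na(sm), m, as.numeric(sm))
  }
  pmf_curve(grid, m, profiles[[1L]]$temperature, defined = defined)
}

#' Fit the Lennard-Jones well depth to a PMF with fixed zero-crossing
#'
#' With the zero-crossing `c` fixed from pair-distance statistics, the well
#' depth is the only free shape parameter: `U(r) = eps g(r) + u0` with
#' `g(r) = 4((c/r)^12 - (c/r)^6)`, linear least squares restricted to the
#' long-range region `r >= c` (the short-range part of a PMF measured
#' between isolated bead pairs does not transfer to beads packed inside a
#' protein). The offset `u0` absorbs the curve's arbitrary energy origin.
#'
#' @param pmf A `pmf_curve` over a pair distance (nm).
#' @param c_fixed Zero-crossing distance (nm).
#' @return List with `eps` (kJ/mol), `u0`, `rms`, `domain`.
#' @export
fit_lj_depth <- function(pmf, c_fixed) {
  ok <- pmf$defined & pmf$x >= c_fixed
  r <- pmf$x[ok]; u <- pmf$U[ok]
  if (length(r) < 3L) stop("PMF does not cover the long-range r >= c region")
  g <- 4 * ((c_fixed / r)^12 - (c_fixed / r)^6)
  fit <- stats::lm(u ~ g)
  eps <- unname(stats::coef(fit)["g"])
  if (!is.finite(eps) || eps <= 0)
    stop("PMF is entirely repulsive on the fit domain; no attractive well")
  list(eps = eps, u0 = unname(stats::coef(fit)["(Intercept)"]),
       rms = sqrt(mean(stats::resid(fit)^2)), domain = range(r))
}

#' Weighted histogram analysis of umbrella-sampling windows
#'
#' Standard self-consistent WHAM for harmonically biased windows: iterates
#' the window free energies to a tolerance of 1e-6 kJ/mol and returns the
#' unbiased PMF, shifted to minimum zero. A single unbiased window reduces
#' to plain Boltzmann inversion of its histogram. Non-overlapping adjacent
#' windows trigger a warning and the result is flagged.
#'
#' @param windows List of windows, each `list(samples, center, stiffness)`
#'   (see [make_umbrella_windows()]).
#' @param temperature Kelvin.
#' @param bin_width Histogram bin width along the coordinate.
#' @param tol Convergence tolerance on the free energies (kJ/mol).
#' @param max_iter Iteration cap.
#' @return A `pmf_curve`; attribute `flagged` is `TRUE` if window overlap
#'   was insufficient, and `f` holds the converged window free energies.
#' @export
wham <- function(windows, temperature = 300, bin_width = 0.005,
                 tol = 1e-6, max_iter = 20000L) {
  stopifnot(length(windows) >= 1L)
  beta <- 1 / (KB * temperature)
  allx <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(allx) / bin_width) * bin_width
  hi <- ceiling(max(allx) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nbin <- length(centers)
  K <- length(windows)
  counts <- matrix(0, nbin, K)
  for (k in seq_len(K)) {
    h <- table(cut(windows[[k]]$samples, edges, include.lowest = TRUE,
                   labels = FALSE))
    counts[as.integer(names(h)), k] <- as.integer(h)
  }
  flagged <- FALSE
  if (K > 1L) {
    ord <- order(vapply(windows, `[[`, 0, "center"))
    for (k in seq_len(K - 1L)) {
      a <- counts[, ord[k]] > 0; b <- counts[, ord[k + 1L]] > 0
      if (!any(a & b)) flagged <- TRUE
    }
    if (flagged)
      warning("insufficient overlap between adjacent umbrella windows")
  }
  Nk <- colSums(counts)
  nm <- rowSums(counts)
  bias <- vapply(seq_len(K), function(k)
    0.5 * windows[[k]]$stiffness * (centers - windows[[k]]$center)^2,
    numeric(nbin))                       # nbin x K
  ebias <- exp(-beta * bias)
  f <- rep(0, K)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(ebias %*% (Nk * exp(beta * f)))
    p <- ifelse(denom > 0, nm / denom, 0)
    fnew <- -log(colSums(p * ebias)) / beta
    fnew <- fnew - fnew[1L]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) break
  }
  defined <- nm > 0 & is.finite(p) & p > 0
  U <- ifelse(defined, -log(p) / beta, NA_real_)
  out <- pmf_curve(centers, U, temperature, defined = defined)
  attr(out, "flagged") <- flagged
  attr(out, "f") <- f
  attr(out, "iterations") <- it
  out
}

#' Read / write a PMF curve as two-column text
#' @param pmf A `pmf_curve`; `file` a path.
#' @param file Path to a two-column (coordinate, energy) text file.
#' @return `write_pmf`: invisibly `file`; `read_pmf`: a `pmf_curve`.
#' @export
write_pmf <- function(pmf, file) {
  utils::write.table(
    data.frame(x = signif(pmf$x[pmf$defined], 7),
               U = signif(pmf$U[pmf$defined], 7)),
    file, row.names = FALSE, col.names = c("# x", "U_kJmol"), quote = FALSE)
  invisible(file)
}

#' @rdname write_pmf
#' @param temperature Kelvin (attached to the curve on read).
#' @export
read_pmf <- function(file, temperature = 300) {
  d <- utils::read.table(file, header = FALSE, skip = 1L)
  pmf_curve(d[[1]], d[[2]], temperature)
}

#' Fit the bonded Gaussian-sum potentials from a structure set
#'
#' Runs the statistics -> Boltzmann inversion -> merge -> fit pipeline for
#' the three angle senses (the two backbone/side senses share one merged
#' parameter set) and the four dihedral types.
#'
#' @param structures List of `aa_structure` objects.
#' @param temperature Kelvin for the inversion.
#' @param n_max Maximum Gaussian terms per fit.
#' @return List with `angles` (named fits: `B-B-B`, `B-B-S`) and
#'   `torsions` (named fits for the four types).
#' @export
parameterize_bonded <- function(structures, temperature = 300, n_max = 6L) {
  ah <- collect_internal_coordinates(structures, "angle")
  invert <- function(h) boltzmann_invert(h, temperature)
  angles <- list()
  if (!"B-B-B" %in% names(ah)) stop("structure set yields no B-B-B angles")
  angles[["B-B-B"]] <- fit_gaussian_sum(invert(ah[["B-B-B"]]), "angle",
                                        n_max)
  side <- intersect(c("B-B-S", "S-B-B"), names(ah))
  if (length(side)) {
    merged <- merge_profiles(lapply(ah[side], invert))
    angles[["B-B-S"]] <- fit_gaussian_sum(merged, "angle", n_max)
  }
  th <- collect_internal_coordinates(structures, "torsion")
  torsions <- lapply(th, function(h)
    fit_gaussian_sum(invert(h), "torsion", n_max))
  list(angles = angles, torsions = torsions)
}
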