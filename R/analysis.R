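# Trajectory observables: optimal rigid-body superposition (Kabsch),
# backbone-bead RMSD time series, per-bead RMSF about the average
# structure, and the crystallographic B-factor conversion.

#' Optimal least-squares superposition of two coordinate sets
#'
#' Kabsch algorithm: the proper rotation and translation minimizing the
#' (optionally weighted) RMSD of `mobile` onto `ref`.
#'
#' @param ref,mobile n x 3 coordinate matrices (nm), equal lengths, n >= 3.
#' @param weights Optional non-negative weights, length n.
#' @return List with `rotation` (3 x 3, det +1), `translation` (so that
#'   `mobile %*% rotation + translation` is aligned onto `ref`), `rmsd`
#'   (nm) and `transformed` (the aligned mobile set).
#' @export
superpose <- function(ref, mobile, weights = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (!all(dim(ref) == dim(mobile)))
    stop("coordinate sets differ in size")
  n <- nrow(ref)
  if (n < 3L) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mu_r <- colSums(ref * w)
  mu_m <- colSums(mobile * w)
  A <- sweep(ref, 2L, mu_r)
  B <- sweep(mobile, 2L, mu_m)
  H <- t(B * w) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  transformed <- sweep(B %*% R, 2L, mu_r, "+")
  rmsd <- sqrt(sum(w * rowSums((transformed - ref)^2)))
  list(rotation = R, translation = mu_r - as.numeric(mu_m %*% R),
       rmsd = rmsd, transformed = transformed)
}

.selection_idx <- function(beads, selection) {
  idx <- switch(selection,
                backbone = which(beads$category == "backbone"),
                protein = which(beads$category != "water"),
                all = seq_len(nrow(beads)),
                stop("unknown selection: ", selection))
  if (!length(idx)) stop("selection '", selection, "' matches no beads")
  idx
}

#' Backbone-bead RMSD time series
#'
#' Per-frame RMSD over the backbone beads (which sit on the Calpha atoms)
#' after optimal superposition onto the reference.
#'
#' @param traj A `cg_trajectory`.
#' @param ref Reference `cg_structure` (or n x 3 matrix matching the
#'   selection).
#' @param selection `"backbone"` (default), `"protein"` or `"all"`.
#' @return Data frame with `time` (ps) and `rmsd` (nm); attributes `mean`,
#'   `sd` and `final` summarize the series.
#' @export
rmsd_series <- function(traj, ref, selection = "backbone") {
  idx <- .selection_idx(traj$beads, selection)
  refp <- if (inherits(ref, "cg_structure"))
    cg_positions(ref)[.selection_idx(ref$beads, selection), , drop = FALSE]
  else as.matrix(ref)
  if (nrow(refp) != length(idx))
    stop("reference and trajectory selections differ in size")
  nf <- dim(traj$positions)[1]
  r <- vapply(seq_len(nf), function(f)
    superpose(refp, traj$positions[f, idx, , drop = TRUE])$rmsd,
    numeric(1))
  out <- data.frame(time = traj$times, rmsd = r)
  attr(out, "mean") <- mean(r)
  attr(out, "sd") <- stats::sd(r)
  attr(out, "final") <- r[nf]
  out
}

#' Per-bead root-mean-square fluctuation
#'
#' Frames are superposed (on the selection) onto the trajectory-average
#' structure, the average is recomputed, and the procedure is iterated
#' twice; RMSF_i is the root-mean-square displacement of bead i about its
#' mean position.
#'
#' @param traj A `cg_trajectory` with at least two frames.
#' @param selection Bead selection used both for fitting and reporting.
#' @return Data frame with `bead`, `resno`, `resid` and `rmsf` (nm).
#' @export
rmsf <- function(traj, selection = "backbone") {
  nf <- dim(traj$positions)[1]
  if (nf < 2L) stop("RMSF needs at least two frames")
  idx <- .selection_idx(traj$beads, selection)
  frames <- lapply(seq_len(nf), function(f)
    traj$positions[f, idx, , drop = TRUE])
  avg <- Reduce(`+`, frames) / nf
  for (it in 1:2) {
    frames <- lapply(frames, function(p) superpose(avg, p)$transformed)
    avg <- Reduce(`+`, frames) / nf
  }
  dev <- vapply(frames, function(p) rowSums((p - avg)^2),
                numeric(length(idx)))
  data.frame(bead = traj$beads$bead[idx], resno = traj$beads$resno[idx],
             resid = traj$beads$resid[idx],
             rmsf = sqrt(rowMeans(dev)))
}

#' Convert a crystallographic B-factor to an RMSF
#'
#' `RMSF = sqrt(3 B / (8 pi^2))`, both in Angstrom units (B in A^2,
#' RMSF in A).
#'
#' @param B Non-negative B-factor(s), A^2.
#' @return RMSF in A.
#' @export
bfactor_to_rmsf <- function(B) {
  if (any(B < 0)) stop("negative B-factor")
  sqrt(3 * B / (8 * pi^2))
}
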