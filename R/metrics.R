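#' Kabsch superposition
#'
#' Least-squares rigid superposition of a mobile point set onto a reference
#' by the Kabsch SVD algorithm. Reflections are excluded (the returned
#' rotation has determinant +1). With weights, the weighted RMSD is
#' minimised.
#'
#' The returned transform maps mobile coordinates as
#' `x' = rotation %*% (x - mobile_centroid) + reference_centroid`.
#'
#' @param mobile,reference `N x 3` matrices, `N >= 3`, not all collinear.
#' @param weights optional non-negative per-point weights.
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (so that `x' = x %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom, after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate superposition: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative, length N, not all zero")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  sv <- svd(crossprod(A * w, B))           # 3x3 covariance H = A' W B
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-12))
    stop("degenerate superposition: points are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(A %*% t(R), 2L, cr, `+`)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  out <- list(rotation = R, translation = as.numeric(cr - R %*% cm),
              rmsd = rmsd)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coord `N x 3` matrix
#' @param sp a `superposition`
#' @return transformed `N x 3` matrix
#' @export
apply_superposition <- function(coord, sp) {
  sweep(as.matrix(coord) %*% t(sp$rotation), 2L, sp$translation, `+`)
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is Kabsch-superposed onto the reference over the selection
#' before the RMSD is taken over that same selection, so the series is
#' invariant under rigid motions of whole frames.
#'
#' @param traj a [trajectory3d]
#' @param reference a [structure3d] (first model used) or `N x 3` matrix.
#' @param selection atom indices; default all atoms.
#' @param fit superpose before measuring (default TRUE).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = traj$topology, selection = NULL,
                        fit = TRUE) {
  stopifnot(inherits(traj, "trajectory3d"))
  ref <- if (inherits(reference, "structure3d")) coords(reference) else
    as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(dim(traj$frames)[1])
  if (length(selection) == 0L) stop("selection resolves to zero atoms")
  refs <- ref[selection, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    m <- traj$frames[selection, , f]
    if (fit) m <- apply_superposition(m, kabsch_superpose(m, refs))
    sqrt(mean(rowSums((m - refs)^2)))
  }, numeric(1))
}

# superpose every frame onto ref over `selection`; returns array like frames
superpose_frames <- function(frames, ref, selection) {
  out <- frames
  for (f in seq_len(dim(frames)[3])) {
    sp <- kabsch_superpose(frames[selection, , f], ref[selection, , drop = FALSE])
    out[, , f] <- apply_superposition(frames[, , f], sp)
  }
  out
}

# iterated-mean reference: start from the raw coordinate mean (invariant
# under frame reordering), superpose all frames to it, average, re-superpose
# (`iterations` passes). Returns list(frames, mean).
iterated_mean_fit <- function(frames, selection, iterations = 2L) {
  ref <- apply(frames, c(1L, 2L), mean)
  fitted <- frames
  for (it in seq_len(iterations)) {
    fitted <- superpose_frames(fitted, ref, selection)
    ref <- apply(fitted, c(1L, 2L), mean)
  }
  list(frames = fitted, mean = ref)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed to an iterated mean structure (two passes by
#' default; `reference = "first"` uses the first frame instead), then
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` is computed per selected atom.
#'
#' @param traj a [trajectory3d] with at least 2 frames.
#' @param selection atom indices (default: all atoms). Both the fit and the
#'   profile use this selection.
#' @param reference `"mean"` (iterated mean structure, default) or `"first"`.
#' @return list of class `fluctuation_profile`: `rmsf` (Angstrom, one entry
#'   per selected atom), `mean` (mean structure coordinates over the
#'   selection), `selection`.
#' @export
rmsf <- function(traj, selection = NULL, reference = c("mean", "first")) {
  stopifnot(inherits(traj, "trajectory3d"))
  reference <- match.arg(reference)
  if (n_frames(traj) < 2L)
    stop("insufficient frames: RMSF needs at least 2")
  if (is.null(selection)) selection <- seq_len(dim(traj$frames)[1])
  sub <- traj$frames[selection, , , drop = FALSE]
  sel <- seq_along(selection)
  if (reference == "mean") {
    fit <- iterated_mean_fit(sub, sel, iterations = 2L)
  } else {
    fr <- superpose_frames(sub, sub[, , 1L], sel)
    fit <- list(frames = fr, mean = apply(fr, c(1L, 2L), mean))
  }
  # N x 3 x F squared deviations; per atom: mean over frames of |dr|^2
  dev2 <- sweep(fit$frames, c(1L, 2L), fit$mean)^2
  out <- list(rmsf = sqrt(apply(dev2, 1L, sum) / dim(sub)[3]),
              mean = fit$mean, selection = selection)
  class(out) <- "fluctuation_profile"
  out
}

#' @export
print.fluctuation_profile <- function(x, ...) {
  cat(sprintf("fluctuation_profile: %d atoms, RMSF %.3f-%.3f A (mean %.3f)\n",
              length(x$rmsf), min(x$rmsf), max(x$rmsf), mean(x$rmsf)))
  invisible(x)
}

#' Inter-atomic distance time series
#'
#' Euclidean distance between two atoms in every frame, without any
#' superposition.
#'
#' @param traj a [trajectory3d]
#' @param i,j atom indices.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
distance_series <- function(traj, i, j) {
  stopifnot(inherits(traj, "trajectory3d"))
  n <- dim(traj$frames)[1]
  if (i < 1L || i > n || j < 1L || j > n) stop("atom index out of range")
  if (i == j) {
    warning("degenerate pair: i == j, returning zeros")
    return(numeric(n_frames(traj)))
  }
  a <- traj$frames[i, , , drop = FALSE]; dim(a) <- dim(a)[2:3]
  b <- traj$frames[j, , , drop = FALSE]; dim(b) <- dim(b)[2:3]
  sqrt(colSums((a - b)^2))
}
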