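#' Build a Calpha-only toy fold
#'
#' Deterministic idealised geometries used as references for the elastic
#' trajectory generator: a straight chain (3.8 A consecutive Calpha
#' spacing), an ideal alpha helix (rise 1.5 A, 100 deg/residue, radius
#' 2.3 A), or a two-chain arrangement of parallel chains 5.5 A apart whose
#' facing residues form a contiguous interface (>= 4 inter-chain pairs under
#' 8 A for n >= 8).
#'
#' @param n_residues total number of residues (>= 3).
#' @param geometry `"chain"`, `"helix"` or `"two_chain"`.
#' @return a [structure3d] with one CA atom per residue (chains A, or A/B).
#' @export
make_toy_fold <- function(n_residues,
                          geometry = c("chain", "helix", "two_chain")) {
  geometry <- match.arg(geometry)
  if (n_residues < 3L) stop("toy fold needs at least 3 residues")
  helix_xyz <- function(n, origin = c(0, 0, 0)) {
    i <- seq_len(n) - 1L
    th <- i * 100 * pi / 180
    cbind(2.3 * cos(th) + origin[1], 2.3 * sin(th) + origin[2],
          1.5 * i + origin[3])
  }
  if (geometry == "chain") {
    xyz <- cbind(3.8 * (seq_len(n_residues) - 1L), 0, 0)
    chain <- rep("A", n_residues); resid <- seq_len(n_residues)
  } else if (geometry == "helix") {
    xyz <- helix_xyz(n_residues)
    chain <- rep("A", n_residues); resid <- seq_len(n_residues)
  } else {
    na <- ceiling(n_residues / 2); nb <- n_residues - na
    xa <- cbind(3.8 * (seq_len(na) - 1L), 0, 0)
    xb <- cbind(3.8 * (seq_len(nb) - 1L), 5.5, 0)
    xyz <- rbind(xa, xb)
    chain <- c(rep("A", na), rep("B", nb))
    resid <- c(seq_len(na), seq_len(nb))
  }
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
                      chain = chain, resid = resid, inscode = "",
                      element = "C", occupancy = 1, bfactor = 0,
                      het = FALSE, stringsAsFactors = FALSE)
  structure3d(atoms, xyz)
}

#' Elastic Gaussian model of a structure's fluctuations
#'
#' Residue-level Gaussian displacement model: each residue fluctuates
#' isotropically in 3-D with per-axis standard deviation `sigma`, and
#' residue pairs may be coupled through a residue-residue displacement
#' correlation matrix. The full 3N x 3N displacement covariance is the
#' Kronecker product `S %x% I3` with `S = corr * outer(sigma, sigma)` (the
#' residue-level matrix is stored as its factor). Frames drawn from the
#' model are independent: the generator targets the occupancy and
#' cross-correlation statistics consumed downstream, not time correlation.
#'
#' @param reference a [structure3d]; the model fluctuates every atom of it
#'   (intended for Calpha-resolution toy folds).
#' @param sigma per-axis displacement standard deviation, Angstrom; scalar
#'   or per-residue vector (stiff core vs. floppy domain profiles).
#' @return object of class `elastic_model` with fields `reference`, `sigma`,
#'   `corr` (R x R, identity initially), `planted_path`, `planted_contacts`.
#' @export
elastic_model <- function(reference, sigma = 0.5) {
  stopifnot(inherits(reference, "structure3d"))
  r <- nrow(residue_table(reference))
  if (length(sigma) == 1L) sigma <- rep(sigma, r)
  if (length(sigma) != r || any(sigma < 0))
    stop("sigma must be a non-negative scalar or one value per residue")
  out <- list(reference = reference, sigma = sigma, corr = diag(r),
              planted_path = NULL,
              planted_contacts = data.frame(i = integer(), j = integer(),
                                            occupancy = numeric()))
  class(out) <- "elastic_model"
  out
}

#' @export
print.elastic_model <- function(x, ...) {
  cat(sprintf(
    "elastic_model: %d residues, sigma %.2f-%.2f A, %d planted contact(s)%s\n",
    length(x$sigma), min(x$sigma), max(x$sigma), nrow(x$planted_contacts),
    if (is.null(x$planted_path)) "" else
      sprintf(", planted path of %d residues", length(x$planted_path))))
  invisible(x)
}

# resolve residue references (indices or "chain:resid" keys) to indices
resolve_residues <- function(reference, res) {
  tab <- residue_table(reference)
  if (is.numeric(res)) {
    idx <- as.integer(res)
    if (any(idx < 1L | idx > nrow(tab))) stop("residue index out of range")
    return(idx)
  }
  idx <- match(res, tab$key)
  if (anyNA(idx))
    stop("residue not found: ", paste(res[is.na(idx)], collapse = ", "))
  idx
}

#' Plant a correlated displacement path into an elastic model
#'
#' Imposes high motional correlation along an ordered residue chain, the
#' statistical signature an allosteric communication pathway leaves in a
#' trajectory. Consecutive path residues receive displacement correlation
#' exactly `rho`; correlation between path residues `a` and `b` decays as
#' `rho^|a-b|` (a Kac-Murdock-Szego structure, positive semidefinite by
#' construction, so the planted value survives unmodified); residues off the
#' path are untouched. An empty path is the identity operation.
#'
#' Consecutive path residues must be within twice the standard 4.5 A contact
#' cutoff in the reference: the sampler pins planted contacts to the cutoff
#' frame by frame, so this check only rejects plants the contact machinery
#' could not realise.
#'
#' @param model an [elastic_model]
#' @param path ordered residue indices or `"chain:resid"` keys (>= 2,
#'   distinct endpoints).
#' @param rho target correlation of consecutive path residues, in (0, 1).
#' @return the modified `elastic_model`.
#' @export
plant_correlated_path <- function(model, path, rho) {
  stopifnot(inherits(model, "elastic_model"))
  if (length(path) == 0L) return(model)
  if (!(is.numeric(rho) && length(rho) == 1L && rho > 0 && rho < 1))
    stop("rho must lie strictly in (0, 1)")
  idx <- resolve_residues(model$reference, path)
  if (length(idx) < 2L) stop("path needs at least 2 residues")
  if (idx[1] == idx[length(idx)]) stop("path endpoints must be distinct")
  if (anyDuplicated(idx)) stop("path visits a residue twice")
  tab <- residue_table(model$reference)
  xyz <- coords(model$reference)[tab$ca, , drop = FALSE]
  d <- sqrt(rowSums((xyz[idx[-1], , drop = FALSE] -
                     xyz[idx[-length(idx)], , drop = FALSE])^2))
  if (any(d > 9))
    stop("consecutive path residues too far apart in the reference (",
         sprintf("%.1f", max(d)), " A > 9 A)")
  k <- length(idx)
  model$corr[idx, idx] <- rho^abs(outer(seq_len(k), seq_len(k), `-`))
  ev <- eigen(model$corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) model$corr <- psd_repair(model$corr)
  model$planted_path <- idx
  model
}

#' Plant contacts with target occupancies
#'
#' Registers residue pairs whose instantaneous contact state (inside or
#' outside the 4.5 A cutoff) the sampler will toggle as an independent
#' Bernoulli(occupancy) draw per frame.
#'
#' @param model an [elastic_model]
#' @param pairs 2-column matrix (or length-2 vector) of residue indices or a
#'   list of length-2 key vectors.
#' @param occupancy target contact occupancy in `[0, 1]`, recycled over pairs.
#' @return the modified `elastic_model`.
#' @export
plant_contact <- function(model, pairs, occupancy) {
  stopifnot(inherits(model, "elastic_model"))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.vector(pairs)) pairs <- matrix(pairs, ncol = 2)
  i <- resolve_residues(model$reference, pairs[, 1])
  j <- resolve_residues(model$reference, pairs[, 2])
  if (any(i == j)) stop("a contact needs two distinct residues")
  occupancy <- rep_len(occupancy, length(i))
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must lie in [0, 1]")
  model$planted_contacts <- rbind(
    model$planted_contacts,
    data.frame(i = i, j = j, occupancy = occupancy))
  model
}

#' Residue-level covariance of an elastic model
#' @param model an [elastic_model]
#' @param full return the 3N x 3N coordinate covariance (`S %x% I3`) instead
#'   of the R x R residue matrix `S`.
#' @return covariance matrix (Angstrom^2)
#' @export
model_covariance <- function(model, full = FALSE) {
  S <- model$corr * outer(model$sigma, model$sigma)
  if (full) S %x% diag(3) else S
}

#' Repair a correlation matrix to positive semidefiniteness
#'
#' Eigenvalue clipping at zero followed by renormalisation to unit diagonal.
#' Used when hand-edited correlation structures leave the PSD cone.
#'
#' @param C symmetric matrix with unit diagonal.
#' @return nearest-by-clipping PSD correlation matrix.
#' @export
psd_repair <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / outer(d, d)
  (out + t(out)) / 2
}

#' Sample a synthetic trajectory from an elastic model
#'
#' Frames are the reference coordinates plus zero-mean Gaussian
#' displacements with the model covariance, drawn independently per frame
#' from a fixed eigenfactor of the residue-level covariance; identical
#' `(model, seed)` give bit-identical trajectories. Planted contacts are
#' realised in two steps: the reference geometry is first relaxed once so
#' that every planted pair sits at the in-contact distance (4.0 A, just
#' inside the 4.5 A cutoff), then each frame pins the pair at 4.0 A with
#' probability `occupancy` and pushes it out to 6.0 A otherwise, moving both
#' partners symmetrically along their separation axis. Relaxing first keeps
#' the per-frame adjustments at noise scale, so planted correlations
#' survive the contact realisation. Because pins can share residues, the
#' distance constraints are enforced by Gauss-Seidel projection sweeps.
#'
#' @param model an [elastic_model] (covariance must be PSD).
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed (same seed, same trajectory).
#' @param dt ns per frame.
#' @return a [trajectory3d]
#' @export
sample_trajectory <- function(model, n_frames, seed = 1L, dt = 0.1) {
  stopifnot(inherits(model, "elastic_model"), n_frames >= 1L)
  S <- model_covariance(model)
  e <- eigen(S, symmetric = TRUE)
  tolv <- 1e-10 * max(abs(e$values), 1)
  if (min(e$values) < -tolv)
    stop(sprintf("covariance not positive semidefinite (smallest eigenvalue %.3g)",
                 min(e$values)))
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  ref <- coords(model$reference)
  tab <- residue_table(model$reference)
  if (anyNA(tab$ca)) stop("elastic model requires a CA atom per residue")
  r <- nrow(tab); f <- as.integer(n_frames)
  pc0 <- model$planted_contacts
  if (nrow(pc0) > 0L) {
    # Relax the reference so planted pairs sit at the in-contact distance
    # (whole-residue shifts), with an excluded-volume term keeping every
    # other non-neighbour residue pair at >= 5.5 A so the relaxation cannot
    # crumple the fold into accidental persistent contacts.
    a2r <- atom2residue(model$reference)
    ca <- tab$ca
    planted_key <- paste(pmin(pc0$i, pc0$j), pmax(pc0$i, pc0$j))
    adjacent <- function(i, j)
      tab$chain[i] == tab$chain[j] & abs(tab$resid[i] - tab$resid[j]) <= 1L
    move_pair <- function(ri, rj, target, only_closer = FALSE) {
      dvec <- ref[ca[rj], ] - ref[ca[ri], ]
      d <- sqrt(sum(dvec^2)); if (d < 1e-9) d <- 1e-9
      if (only_closer && d >= target) return(invisible())
      shift <- dvec * ((target - d) / 2) / d
      ref[a2r == ri, ] <<- sweep(ref[a2r == ri, , drop = FALSE], 2L, shift)
      ref[a2r == rj, ] <<- sweep(ref[a2r == rj, , drop = FALSE], 2L, -shift)
    }
    for (sweep in 1:80) {
      for (k in seq_len(nrow(pc0))) move_pair(pc0$i[k], pc0$j[k], 4.0)
      dm <- as.matrix(stats::dist(ref[ca, , drop = FALSE]))
      close <- which(upper.tri(dm) & dm < 5.5, arr.ind = TRUE)
      for (k in seq_len(nrow(close))) {
        ri <- close[k, 1]; rj <- close[k, 2]
        if (paste(min(ri, rj), max(ri, rj)) %in% planted_key) next
        if (adjacent(ri, rj)) next
        move_pair(ri, rj, 5.5, only_closer = TRUE)
      }
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  # displacement per axis: F x R matrix Z %*% t(L)
  disp <- array(0, dim = c(r, 3L, f))
  for (a in 1:3) {
    D <- matrix(stats::rnorm(f * r), f, r) %*% t(L)   # F x R
    disp[, a, ] <- t(D)
  }
  frames <- array(ref, dim = c(nrow(ref), 3L, f)) + disp[rep_ca_map(model$reference), , , drop = FALSE]
  pc <- model$planted_contacts
  if (nrow(pc) > 0L) {
    states <- matrix(stats::runif(f * nrow(pc)) < rep(pc$occupancy, each = f),
                     f, nrow(pc))
    ca <- tab$ca
    for (sweep in 1:12) {
      for (k in seq_len(nrow(pc))) {
        ai <- ca[pc$i[k]]; aj <- ca[pc$j[k]]
        target <- ifelse(states[, k], 4.0, 6.0)
        vi <- frames[ai, , , drop = FALSE]; dim(vi) <- c(3L, f)
        vj <- frames[aj, , , drop = FALSE]; dim(vj) <- c(3L, f)
        dvec <- vj - vi
        dist <- sqrt(colSums(dvec^2))
        dist[dist < 1e-9] <- 1e-9
        # out-of-contact frames already beyond the target need no push
        adj <- (target - dist) / 2
        adj[!states[, k] & dist >= 6.0] <- 0
        shift <- dvec * rep(adj / dist, each = 3L)
        frames[ai, , ] <- vi - shift
        frames[aj, , ] <- vj + shift
      }
    }
  }
  trajectory3d(model$reference, frames, dt = dt)
}

# atom -> residue row map (identity for CA-only folds; general otherwise)
rep_ca_map <- function(reference) atom2residue(reference)

#' Synthetic two-domain complex (labelled stand-in)
#'
#' Builds a compact, entirely synthetic Calpha-resolution complex of a large
#' G-domain-like chain A (residues numbered from 1) and a smaller
#' RBD-like chain B (residues numbered from `b_start`, so a residue 113
#' exists for span measurements). Residues fill a cubic lattice (3.8 A
#' spacing) inside two touching spheres, giving each chain a solvent-exposed
#' surface and a buried core so that surface-area and interface machinery
#' can be exercised end to end. The geometry is not derived from any
#' deposited structure; every number measured on it is a property of this
#' synthetic object only.
#'
#' @param r_a,r_b sphere radii of the two chains, Angstrom.
#' @param gap surface-to-surface separation of the two spheres, Angstrom
#'   (small positive value: the lattice discretisation adds ~2.5 A, so the
#'   default keeps the closest atom pair near 3.5 A — touching, not
#'   clashing).
#' @param b_start first residue number of chain B (default 56).
#' @return a [structure3d] with chains A and B.
#' @export
make_synthetic_complex <- function(r_a = 12, r_b = 9.5, gap = 1,
                                   b_start = 56L) {
  lattice_sphere <- function(radius, center) {
    g <- 3.8 * seq(-floor(radius / 3.8), floor(radius / 3.8))  # symmetric grid
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- pts[sqrt(rowSums(pts^2)) <= radius, , drop = FALSE]
    pts <- pts[order(pts[, 3], pts[, 2], pts[, 1]), , drop = FALSE]
    sweep(pts, 2L, center, `+`)
  }
  xa <- lattice_sphere(r_a, c(0, 0, 0))
  xb <- lattice_sphere(r_b, c(r_a + r_b + gap, 0, 0))
  n <- nrow(xa) + nrow(xb)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", resname = "ALA",
    chain = c(rep("A", nrow(xa)), rep("B", nrow(xb))),
    resid = c(seq_len(nrow(xa)), b_start + seq_len(nrow(xb)) - 1L),
    inscode = "", element = "C", occupancy = 1, bfactor = 0, het = FALSE,
    stringsAsFactors = FALSE)
  structure3d(atoms, rbind(xa, xb))
}
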