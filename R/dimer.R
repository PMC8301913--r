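#' Crystallographic symmetry operator
#'
#' An explicit rotation + translation pair acting on orthogonal (Cartesian)
#' coordinates: `x' = R x + t`. Full space-group expansion is deliberately
#' out of scope — only explicit operators (typically a single 2-fold) are
#' applied, which keeps every applied transform auditable.
#'
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation length-3 vector, Angstrom.
#' @param check_twofold additionally require the operator composed with
#'   itself to be the identity (max deviation 1e-3).
#' @return object of class `symmetry_operator`.
#' @export
symmetry_operator <- function(rotation, translation = c(0, 0, 0),
                              check_twofold = FALSE) {
  R <- as.matrix(rotation)
  t <- as.numeric(translation)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(R) < 0) stop("operator is a reflection (det -1)")
  if (check_twofold) {
    R2 <- R %*% R
    t2 <- as.numeric(R %*% t + t)
    if (max(abs(R2 - diag(3))) > 1e-3 || max(abs(t2)) > 1e-3)
      stop("operator is not a 2-fold (op o op differs from identity)")
  }
  out <- list(rotation = R, translation = t)
  class(out) <- "symmetry_operator"
  out
}

#' Rotation operator about a coordinate axis
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angle_deg rotation angle, degrees.
#' @param translation optional translation, Angstrom.
#' @return a [symmetry_operator]
#' @export
axis_rotation <- function(axis = c("z", "x", "y"), angle_deg,
                          translation = c(0, 0, 0)) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  R <- switch(axis,
    z = matrix(c(c2, -s2, 0, s2, c2, 0, 0, 0, 1), 3, 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, c2, -s2, 0, s2, c2), 3, 3, byrow = TRUE),
    y = matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3, 3, byrow = TRUE))
  symmetry_operator(R, translation)
}

transform_coords <- function(xyz, op) {
  sweep(xyz %*% t(op$rotation), 2L, op$translation, `+`)
}

# minimum inter-group atom distance; heavy atoms only
min_cross_distance <- function(xyzA, xyzB) {
  best <- Inf
  # block over A to bound memory on large structures
  step <- 2000L
  for (s in seq(1L, nrow(xyzA), by = step)) {
    blk <- xyzA[s:min(s + step - 1L, nrow(xyzA)), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(xyzB^2), `+`) -
      2 * tcrossprod(blk, xyzB)
    best <- min(best, sqrt(max(min(d2), 0)))
  }
  best
}

check_clashes <- function(xyzA, xyzB, what = "protomers") {
  dmin <- min_cross_distance(xyzA, xyzB)
  if (dmin < 1.5)
    stop(sprintf("steric clash between %s: minimum distance %.2f A < 1.5 A",
                 what, dmin))
  if (dmin < 2.5)
    warning(sprintf("close contact between %s: minimum distance %.2f A",
                    what, dmin))
  invisible(dmin)
}

next_free_chains <- function(used, n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  free <- setdiff(pool, used)
  if (length(free) < n) stop("no free chain identifiers left")
  free[seq_len(n)]
}

#' Apply a symmetry operator to generate a symmetry mate
#'
#' Returns the original structure plus its transformed copy with renamed
#' chains (a crystallographic dimer when `op` is the relevant 2-fold).
#' Inter-copy heavy-atom distances below 1.5 A raise a clash error, below
#' 2.5 A a warning.
#'
#' @param x a [structure3d] (single model).
#' @param op a [symmetry_operator].
#' @param chain_map optional named character vector renaming the copy's
#'   chains; defaults to the next unused single-character ids (so output
#'   remains PDB-writable).
#' @return a [structure3d] with both copies; attribute `chain_map` records
#'   the renaming.
#' @export
apply_symmetry <- function(x, op, chain_map = NULL) {
  stopifnot(inherits(x, "structure3d"), inherits(op, "symmetry_operator"))
  chains <- unique(x$atoms$chain)
  if (is.null(chain_map)) {
    chain_map <- stats::setNames(next_free_chains(chains, length(chains)),
                                 chains)
  } else {
    if (!all(chains %in% names(chain_map)))
      stop("chain_map must cover every chain")
    if (any(chain_map %in% chains) || anyDuplicated(chain_map))
      stop("chain-name collision in chain_map")
  }
  xyz <- coords(x)
  txyz <- transform_coords(xyz, op)
  heavy <- x$atoms$element != "H"
  check_clashes(xyz[heavy, , drop = FALSE], txyz[heavy, , drop = FALSE])
  mate <- x$atoms
  mate$chain <- unname(chain_map[mate$chain])
  mate$serial <- mate$serial + max(x$atoms$serial)
  atoms <- rbind(x$atoms, mate)
  rownames(atoms) <- NULL
  out <- structure3d(atoms, rbind(xyz, txyz), crystal = x$crystal)
  attr(out, "chain_map") <- chain_map
  out
}

#' Build a two-protomer dimer model by superposition onto a template
#'
#' Reproduces the standard crystallographic modelling move: a complex
#' (e.g., Ras G domain + Raf) is superposed, via a Kabsch fit on an anchor
#' selection (by default the Ras G domain Calpha trace, residues 1-166),
#' onto each protomer of a template dimer, and the two placed copies are
#' assembled into a dimer model with unique chain ids.
#'
#' @param complex a [structure3d], the monomeric complex to place twice.
#' @param template a [structure3d] holding a two-protomer dimer.
#' @param anchor_chain chain of `complex` carrying the anchor residues.
#' @param anchor_resid anchor residue numbers (default 1:166).
#' @param template_anchor_chains length-2 character: the chain of each
#'   template protomer equivalent to `anchor_chain`.
#' @param anchor_atom atom name used for the fit (default `"CA"`).
#' @return list of class `dimer_model`: `assembly` (a [structure3d]),
#'   `protomer_map` (chain renaming per protomer), `anchor_rmsd` (per
#'   protomer, Angstrom), `n_anchor` (anchor atom count).
#' @export
build_dimer_by_superposition <- function(complex, template, anchor_chain,
                                         anchor_resid = 1:166,
                                         template_anchor_chains,
                                         anchor_atom = "CA") {
  stopifnot(inherits(complex, "structure3d"),
            inherits(template, "structure3d"),
            length(template_anchor_chains) == 2L)
  ca <- complex$atoms
  selc <- select_atoms(complex, chain = anchor_chain, resid = anchor_resid,
                       atom_names = anchor_atom)
  placed <- list()
  rmsds <- numeric(2)
  maps <- list()
  used <- character()
  for (k in 1:2) {
    tch <- template_anchor_chains[k]
    ta <- template$atoms
    hit <- which(ta$chain == tch & ta$resid %in% anchor_resid &
                   ta$name == anchor_atom)
    # align by residue identity
    m <- match(ca$resid[selc], ta$resid[hit])
    if (anyNA(m)) {
      missing <- ca$resid[selc][is.na(m)]
      stop("anchor residues missing from template chain ", tch, ": ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) " ...")
    }
    selt <- hit[m]
    sp <- kabsch_superpose(coords(complex)[selc, , drop = FALSE],
                           coords(template)[selt, , drop = FALSE])
    rmsds[k] <- sp$rmsd
    xyz <- apply_superposition(coords(complex), sp)
    atoms <- complex$atoms
    cmap <- stats::setNames(next_free_chains(used, length(unique(atoms$chain))),
                            unique(atoms$chain))
    atoms$chain <- unname(cmap[atoms$chain])
    used <- c(used, unname(cmap))
    maps[[k]] <- cmap
    placed[[k]] <- list(atoms = atoms, xyz = xyz)
  }
  atoms <- rbind(placed[[1]]$atoms, placed[[2]]$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  xyz <- rbind(placed[[1]]$xyz, placed[[2]]$xyz)
  heavy1 <- placed[[1]]$atoms$element != "H"
  heavy2 <- placed[[2]]$atoms$element != "H"
  check_clashes(placed[[1]]$xyz[heavy1, , drop = FALSE],
                placed[[2]]$xyz[heavy2, , drop = FALSE])
  out <- list(assembly = structure3d(atoms, xyz),
              protomer_map = maps, anchor_rmsd = rmsds,
              n_anchor = length(selc))
  class(out) <- "dimer_model"
  out
}

#' @export
print.dimer_model <- function(x, ...) {
  cat(sprintf("dimer_model: %d atoms, anchor RMSD %.3f / %.3f A over %d atoms\n",
              n_atoms(x$assembly), x$anchor_rmsd[1], x$anchor_rmsd[2],
              x$n_anchor))
  invisible(x)
}

parse_atom_spec <- function(spec) {
  p <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(p) == 2L) p <- c(p, "CA")
  if (length(p) != 3L)
    stop("atom spec must be 'chain:resid' or 'chain:resid:atom': ", spec)
  list(chain = p[1], resid = as.integer(p[2]), name = p[3])
}

#' Distance between two named atoms of an assembly
#'
#' Measures cross-assembly spans such as the separation of the two
#' galectin-pocket aspartates (D113 and D113') across a two-fold dimer.
#'
#' @param x a [structure3d] or `dimer_model`.
#' @param a,b atom specs `"chain:resid"` (Calpha implied) or
#'   `"chain:resid:atom"`.
#' @return distance, Angstrom.
#' @export
measure_span <- function(x, a, b) {
  if (inherits(x, "dimer_model")) x <- x$assembly
  stopifnot(inherits(x, "structure3d"))
  locate <- function(spec) {
    s <- parse_atom_spec(spec)
    hit <- which(x$atoms$chain == s$chain & x$atoms$resid == s$resid &
                   x$atoms$name == s$name)
    if (length(hit) == 0L) stop("atom not found: ", spec)
    hit[1]
  }
  ia <- locate(a); ib <- locate(b)
  sqrt(sum((coords(x)[ia, ] - coords(x)[ib, ])^2))
}
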