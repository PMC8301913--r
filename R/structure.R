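#' Molecular structure container
#'
#' A `structure3d` holds an ordered atom table plus one or more models of
#' Cartesian coordinates, mirroring the content of a (possibly multi-model)
#' PDB file. Author residue numbering is preserved verbatim; downstream code
#' addresses residues by `(chain, resid, inscode)` identity and keeps its own
#' 0/1-based index maps.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resid`, `inscode`, `element`, `occupancy`, `bfactor` (one row per atom,
#'   file order).
#' @param coord numeric array `N x 3 x M` (Angstrom) of `M` model coordinates,
#'   or an `N x 3` matrix for a single model.
#' @param crystal optional list with elements `cell` (numeric length 6) and
#'   `operators` (list of `symmetry_operator`).
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, coord, crystal = NULL) {
  if (is.matrix(coord)) coord <- array(coord, dim = c(nrow(coord), 3L, 1L))
  stopifnot(is.data.frame(atoms), length(dim(coord)) == 3L, dim(coord)[2] == 3L)
  need <- c("serial", "name", "resname", "chain", "resid", "inscode",
            "element", "occupancy", "bfactor")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: zero atoms")
  if (nrow(atoms) != dim(coord)[1])
    stop("coordinate array has ", dim(coord)[1], " atoms but atom table has ",
         nrow(atoms))
  if (!all(is.finite(coord))) stop("non-finite coordinates")
  if (any(is.na(atoms$chain) | atoms$chain == ""))
    stop("every atom must carry a chain identifier")
  key <- paste(atoms$chain, atoms$resid, atoms$inscode, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) atom identity: ",
         key[duplicated(key)][1])
  out <- list(atoms = atoms, coord = coord, crystal = crystal)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d model(s), chains: %s\n",
              n_atoms(x), n_models(x),
              paste(unique(x$atoms$chain), collapse = " ")))
  if (!is.null(x$crystal))
    cat(sprintf("  crystal: %d symmetry operator(s)\n",
                length(x$crystal$operators)))
  invisible(x)
}

#' @rdname structure3d
#' @param x a `structure3d`
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname structure3d
#' @export
n_models <- function(x) dim(x$coord)[3]

#' Coordinates of one model
#'
#' @param x a `structure3d`
#' @param model model number (1-based)
#' @return `N x 3` matrix
#' @export
coords <- function(x, model = 1L) {
  if (model < 1L || model > n_models(x)) stop("model out of range")
  m <- x$coord[, , model, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Replace coordinates of a structure (single model)
#' @param x a `structure3d`
#' @param coord `N x 3` matrix
#' @return modified `structure3d` with one model
#' @export
set_coords <- function(x, coord) {
  stopifnot(nrow(coord) == n_atoms(x), ncol(coord) == 3L)
  x$coord <- array(as.numeric(coord), dim = c(nrow(coord), 3L, 1L))
  x
}

#' Residue table of a structure
#'
#' One row per residue in stable `(chain, resid, inscode)` order (chains in
#' order of first appearance, residues by author number within chain). The
#' row number is the internal 1-based residue index used by all residue-level
#' matrices.
#'
#' @param x a `structure3d`
#' @return data.frame with columns `chain`, `resid`, `inscode`, `resname`,
#'   `key` (label `chain:resid`), and `ca` (atom index of the alpha carbon,
#'   NA if absent).
#' @export
residue_table <- function(x) {
  a <- x$atoms
  key <- paste(a$chain, a$resid, a$inscode, sep = "\r")
  first <- !duplicated(key)
  chain_rank <- match(a$chain, unique(a$chain))
  ord <- order(chain_rank[first], a$resid[first], a$inscode[first])
  idx <- which(first)[ord]
  res <- data.frame(chain = a$chain[idx], resid = a$resid[idx],
                    inscode = a$inscode[idx], resname = a$resname[idx],
                    stringsAsFactors = FALSE)
  res$key <- paste0(res$chain, ":", res$resid,
                    ifelse(res$inscode == "", "", res$inscode))
  ca <- rep(NA_integer_, nrow(res))
  is_ca <- a$name == "CA" & a$element != "CA"  # exclude calcium ions
  rkey <- paste(res$chain, res$resid, res$inscode, sep = "\r")
  hit <- match(key[is_ca], rkey)
  ca[hit[!is.na(hit)]] <- which(is_ca)[!is.na(hit)]
  res$ca <- ca
  res
}

#' Map each atom to its residue index
#' @param x a `structure3d`
#' @return integer vector, length `n_atoms(x)`, of rows into `residue_table(x)`
#' @export
atom2residue <- function(x) {
  a <- x$atoms
  res <- residue_table(x)
  match(paste(a$chain, a$resid, a$inscode, sep = "\r"),
        paste(res$chain, res$resid, res$inscode, sep = "\r"))
}

#' Trajectory container
#'
#' Ordered frames of coordinates over the fixed atom set of a topology
#' structure, with a time-per-frame mapping used by all windowing logic.
#'
#' @param topology a `structure3d` (its first model is the reference frame).
#' @param frames numeric array `N x 3 x F` of coordinates (Angstrom).
#' @param dt time per frame in ns (> 0). Defaults to 0.1 ns when a file
#'   format carries no time information.
#' @return object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, frames, dt = 0.1) {
  stopifnot(inherits(topology, "structure3d"))
  if (is.matrix(frames)) frames <- array(frames, dim = c(nrow(frames), 3L, 1L))
  if (dim(frames)[1] != n_atoms(topology))
    stop("frame atom count (", dim(frames)[1], ") does not match topology (",
         n_atoms(topology), ")")
  if (!(is.numeric(dt) && length(dt) == 1L && dt > 0))
    stop("dt must be a single positive number (ns/frame)")
  if (dim(frames)[3] < 1L) stop("trajectory needs at least one frame")
  out <- list(topology = topology, frames = frames, dt = dt)
  class(out) <- "trajectory3d"
  out
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat(sprintf("trajectory3d: %d frames x %d atoms, dt = %g ns (%g ns total)\n",
              n_frames(x), dim(x$frames)[1], x$dt, n_frames(x) * x$dt))
  invisible(x)
}

#' @rdname trajectory3d
#' @param x a `trajectory3d`
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' Extract one frame as an `N x 3` matrix
#' @param x a `trajectory3d`
#' @param i frame number (1-based)
#' @export
frame_coords <- function(x, i) {
  if (i < 1L || i > n_frames(x)) stop("frame index out of range")
  m <- x$frames[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}
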