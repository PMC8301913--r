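#' Read a structure from a PDB file
#'
#' Parses ATOM and HETATM records (via bio3d) into a [structure3d]. Alternate
#' locations other than blank or 'A' are dropped (first conformer wins).
#' Multi-MODEL files yield one coordinate model per MODEL block; all models
#' must share the atom ordering of the first. CRYST1 cell parameters and
#' REMARK 290 crystallographic symmetry operators, when present, are captured
#' into `$crystal`.
#'
#' @param path PDB file path.
#' @param multi read all MODEL blocks (default TRUE).
#' @return a [structure3d]
#' @export
read_structure <- function(path, multi = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: no atoms in ", path)
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nm <- nrow(xyz)
  n <- nrow(a)
  frames <- array(NA_real_, dim = c(n, 3L, nm))
  for (m in seq_len(nm))
    frames[, , m] <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- a$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- guess_element(a$elety[bad])
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, resname = a$resid, chain = chain,
    resid = a$resno,
    inscode = ifelse(is.na(a$insert), "", a$insert),
    element = toupper(elem),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms <- atoms[keep, , drop = FALSE]
  frames <- frames[keep, , , drop = FALSE]
  if (!all(is.finite(frames)))
    stop("malformed coordinate field in '", path, "' (non-numeric atom ",
         atoms$serial[which(!is.finite(frames[, 1, 1]))[1]], ")")
  structure3d(atoms, frames, crystal = read_crystal_records(path))
}

# element symbol from an atom name, PDB convention: first alphabetic
# character after stripping leading digits; two-letter symbols only for
# common hetero elements.
guess_element <- function(name) {
  nm <- toupper(gsub("^[0-9 ]+", "", name))
  # names like CA/CB are carbons; only a whole-name match on a hetero-element
  # symbol is taken as two-letter (ZN, FE, ...). CA-the-ion must carry an
  # explicit element column to be recognised as calcium.
  two <- c("ZN", "FE", "MG", "MN", "CL", "BR", "NA", "CU", "NI", "SE")
  out <- substr(nm, 1L, 1L)
  whole <- nm %in% two
  out[whole] <- nm[whole]
  out
}

# CRYST1 + REMARK 290 SMTRY parser. Returns NULL when absent.
read_crystal_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL
  if (length(cr) > 0) {
    f <- suppressWarnings(as.numeric(c(
      substr(cr[1], 7, 15), substr(cr[1], 16, 24), substr(cr[1], 25, 33),
      substr(cr[1], 34, 40), substr(cr[1], 41, 47), substr(cr[1], 48, 54))))
    if (all(is.finite(f))) cell <- f
  }
  sm <- grep("^REMARK 290\\s+SMTRY", lines, value = TRUE)
  ops <- NULL
  if (length(sm) > 0) {
    rows <- lapply(sm, function(l) {
      p <- strsplit(trimws(sub("^REMARK 290\\s+", "", l)), "\\s+")[[1]]
      # SMTRYn  opnum  r1 r2 r3  t
      list(row = as.integer(sub("SMTRY", "", p[1])), op = as.integer(p[2]),
           v = as.numeric(p[3:6]))
    })
    opnums <- sort(unique(vapply(rows, `[[`, 1L, "op")))
    ops <- lapply(opnums, function(k) {
      R <- matrix(0, 3, 3); t <- numeric(3)
      for (r in rows) if (r$op == k) {
        R[r$row, ] <- r$v[1:3]; t[r$row] <- r$v[4]
      }
      symmetry_operator(R, t, check_twofold = FALSE)
    })
  }
  if (is.null(cell) && is.null(ops)) return(NULL)
  list(cell = cell, operators = ops)
}

#' Write a structure to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks. Coordinates are
#' written at the PDB's fixed 3-decimal precision, so a write/read round trip
#' is exact at that precision.
#'
#' @param x a [structure3d]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  nm <- n_models(x)
  xyz <- t(apply(x$coord, 3L, function(m) as.vector(t(m))))
  if (nm == 1L) xyz <- matrix(xyz, nrow = 1L)
  a <- x$atoms
  het <- if (is.null(a$het)) rep(FALSE, nrow(a)) else a$het
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   insert = ifelse(a$inscode == "", NA, a$inscode),
                   o = a$occupancy, b = a$bfactor, elesy = a$element)
  invisible(path)
}

#' Read a trajectory
#'
#' Reads DCD (binary, via bio3d) or multi-model PDB coordinate files against
#' a fixed topology. Frame order is preserved as stored. PDB and DCD headers
#' carry no reliable time step, so `dt` defaults to 0.1 ns/frame and should
#' be overridden to match the data.
#'
#' @param path DCD or multi-model PDB file.
#' @param topology a [structure3d] giving the atom set.
#' @param dt time per frame, ns.
#' @return a [trajectory3d]
#' @export
read_trajectory <- function(path, topology, dt = 0.1) {
  stopifnot(inherits(topology, "structure3d"))
  n <- n_atoms(topology)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                    error = function(e) stop("DCD read error in '", path,
                                             "': ", conditionMessage(e)))
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
    if (ncol(xyz) != 3L * n)
      stop("topology mismatch: trajectory has ", ncol(xyz) / 3,
           " atoms, topology has ", n)
    f <- nrow(xyz)
    frames <- array(NA_real_, dim = c(n, 3L, f))
    for (i in seq_len(f))
      frames[, , i] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  } else if (ext == "xtc") {
    stop("XTC reading is not supported; supply DCD or multi-model PDB")
  } else {
    s <- read_structure(path, multi = TRUE)
    if (n_atoms(s) != n)
      stop("topology mismatch: trajectory file has ", n_atoms(s),
           " atoms, topology has ", n)
    frames <- s$coord
  }
  trajectory3d(topology, frames, dt = dt)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a [trajectory3d]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory3d"))
  s <- traj$topology
  s$coord <- traj$frames
  write_structure(s, path)
}

#' Select atoms of a structure
#'
#' Resolves a selection over chain / residue range / atom-name class to a
#' deterministic, ordered atom index list (stable `(chain, resid)` order;
#' chains ordered by first appearance). Selections compose as intersections.
#'
#' @param x a [structure3d]
#' @param chain optional chain id(s).
#' @param resid optional residue numbers (e.g. `1:166`).
#' @param atom_names optional atom name(s), e.g. `"CA"`.
#' @param calpha shortcut for `atom_names = "CA"` restricted to amino-acid
#'   alpha carbons (exactly one index per standard residue).
#' @param heavy drop hydrogens.
#' @return integer vector of atom indices into `x$atoms`.
#' @export
select_atoms <- function(x, chain = NULL, resid = NULL, atom_names = NULL,
                         calpha = FALSE, heavy = FALSE) {
  stopifnot(inherits(x, "structure3d"))
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  if (calpha) keep <- keep & a$name == "CA" & a$element == "C"
  if (heavy) keep <- keep & a$element != "H"
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection resolves to zero atoms")
  chain_rank <- match(a$chain, unique(a$chain))
  idx[order(chain_rank[idx], a$resid[idx], a$inscode[idx], idx)]
}
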