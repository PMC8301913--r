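# Bondi (1964) van der Waals radii, Angstrom. The radii set is printed in
# report headers because buried-area numbers are sensitive to it.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                "F" = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
                ZN = 1.39, MG = 1.73, MN = 1.73, FE = 1.40, "NA" = 2.27,
                K = 2.75, CA = 2.31, CU = 1.40, NI = 1.63)

# deterministic quasi-uniform unit-sphere points (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a solvent probe over the van der Waals surface by testing a
#' deterministic Fibonacci lattice of sphere points per atom against all
#' neighbouring expanded spheres. Areas are exact in the limit of many
#' points; at the default 960 points the quadrature error on smooth surfaces
#' is well under 1%.
#'
#' @param x a [structure3d] (first model used).
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sphere test points per atom.
#' @param include_het include HETATM records (waters, ions, ligands);
#'   excluded by default since burial statistics change with them.
#' @param atoms optional atom index subset to compute over (overrides
#'   `include_het` filtering).
#' @return list of class `sasa_result`: `area` (per-atom, Angstrom^2, zero
#'   for atoms outside the computed subset), `total`, `atoms` (indices
#'   used), `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(x, probe = 1.4, n_points = 960L, include_het = FALSE,
                 atoms = NULL) {
  stopifnot(inherits(x, "structure3d"), probe >= 0, n_points >= 12L)
  if (is.null(atoms)) {
    atoms <- seq_len(n_atoms(x))
    if (!include_het && !is.null(x$atoms$het)) atoms <- which(!x$atoms$het)
  }
  el <- toupper(x$atoms$element[atoms])
  rad <- .vdw_radii[el]
  if (anyNA(rad))
    stop("no van der Waals radius for element '",
         el[which(is.na(rad))[1]], "' (atom serial ",
         x$atoms$serial[atoms[which(is.na(rad))[1]]], ")")
  xyz <- coords(x)[atoms, , drop = FALSE]
  R <- unname(rad) + probe
  n <- length(atoms)
  pts <- fibonacci_sphere(n_points)
  area <- numeric(n)
  # neighbour pairs within touching distance of expanded spheres
  maxR <- max(R)
  nb <- vector("list", n)
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n)) {
      cand <- which(d[i, ] < R[i] + R & seq_len(n) != i)
      nb[[i]] <- cand[order(d[i, cand])]
    }
  }
  for (i in seq_len(n)) {
    P <- pts * R[i]
    P <- sweep(P, 2L, xyz[i, ], `+`)
    alive <- rep(TRUE, n_points)
    for (j in nb[[i]]) {
      if (!any(alive)) break
      dj <- sweep(P[alive, , drop = FALSE], 2L, xyz[j, ], `-`)
      alive[alive] <- rowSums(dj^2) >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(alive) / n_points
  }
  full <- numeric(n_atoms(x))
  full[atoms] <- area
  out <- list(area = full, total = sum(area), atoms = atoms,
              probe_radius = probe, n_sphere_points = as.integer(n_points))
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 over %d atoms (probe %.1f A, %d points, Bondi radii)\n",
              x$total, length(x$atoms), x$probe_radius, x$n_sphere_points))
  invisible(x)
}

subset_structure <- function(x, atoms) {
  a <- x$atoms[atoms, , drop = FALSE]
  rownames(a) <- NULL
  structure3d(a, x$coord[atoms, , 1L, drop = TRUE])
}

#' Buried surface area of an interface between two chain groups
#'
#' BSA = (SASA(A alone) + SASA(B alone) - SASA(A and B together)) / 2: the
#' one-sided "interface area" convention of crystallographic interface
#' analysis (half the total accessible area lost on complex formation).
#' Interface residues are those losing more than 0.1 A^2 of accessible area
#' upon complexation.
#'
#' @param x a [structure3d] containing both groups.
#' @param groupA,groupB disjoint, non-empty chain id vectors.
#' @param probe,n_points,include_het passed to [sasa].
#' @param one_sided report the halved (one-sided) burial; `FALSE` reports
#'   the total two-sided loss. Both values are stored in the result.
#' @return list of class `interface_report`: `bsa`, `bsa_two_sided`,
#'   `interface_residues` (list of per-group residue key vectors),
#'   `residue_loss` (data.frame key/group/loss for interface residues),
#'   `probe_radius`, `n_sphere_points`, `radii_set` ("Bondi").
#' @export
buried_surface_area <- function(x, groupA, groupB, probe = 1.4,
                                n_points = 960L, include_het = FALSE,
                                one_sided = TRUE) {
  stopifnot(inherits(x, "structure3d"))
  if (length(intersect(groupA, groupB)) > 0)
    stop("groups must be disjoint")
  chains <- unique(x$atoms$chain)
  for (g in list(groupA, groupB))
    if (length(g) == 0 || !all(g %in% chains))
      stop("each group must name existing chains")
  het_ok <- if (!include_het && !is.null(x$atoms$het)) !x$atoms$het else
    rep(TRUE, n_atoms(x))
  selA <- which(x$atoms$chain %in% groupA & het_ok)
  selB <- which(x$atoms$chain %in% groupB & het_ok)
  sA <- sasa(subset_structure(x, selA), probe, n_points, include_het = TRUE)
  sB <- sasa(subset_structure(x, selB), probe, n_points, include_het = TRUE)
  sAB <- sasa(x, probe, n_points, include_het = include_het,
              atoms = c(selA, selB))
  two_sided <- sA$total + sB$total - sAB$total
  bsa <- two_sided / 2
  # per-residue accessible-area loss
  a2r <- atom2residue(x)
  tab <- residue_table(x)
  iso <- numeric(nrow(tab))
  iso_area <- c(sA$area[seq_along(selA)], sB$area[seq_along(selB)])
  names_idx <- c(selA, selB)
  for (k in seq_along(names_idx))
    iso[a2r[names_idx[k]]] <- iso[a2r[names_idx[k]]] + iso_area[k]
  cplx <- numeric(nrow(tab))
  for (k in names_idx) cplx[a2r[k]] <- cplx[a2r[k]] + sAB$area[k]
  loss <- iso - cplx
  isif <- which(loss > 0.1)
  res_loss <- data.frame(
    key = tab$key[isif],
    group = ifelse(tab$chain[isif] %in% groupA, "A", "B"),
    loss = loss[isif], stringsAsFactors = FALSE)
  out <- list(bsa = if (one_sided) bsa else two_sided,
              bsa_one_sided = bsa, bsa_two_sided = two_sided,
              interface_residues = list(
                A = res_loss$key[res_loss$group == "A"],
                B = res_loss$key[res_loss$group == "B"]),
              residue_loss = res_loss,
              probe_radius = probe, n_sphere_points = as.integer(n_points),
              radii_set = "Bondi")
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: BSA %.1f A^2 one-sided (%.1f two-sided), %d + %d interface residues (probe %.1f A, %s radii)\n",
              x$bsa_one_sided, x$bsa_two_sided,
              length(x$interface_residues$A), length(x$interface_residues$B),
              x$probe_radius, x$radii_set))
  invisible(x)
}

# Kyte-Doolittle hydropathy
.kd_scale <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5,
               MET = 1.9, ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
               TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
               GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)

#' Interface hydrophobicity significance by surface-patch resampling
#'
#' A resampling analog of interface-specificity statistics: the observed
#' score is the mean Kyte-Doolittle hydropathy of the interface residues
#' (both sides); the null draws `n_resamples` random contiguous patches of
#' the same residue count from the solvent-exposed surface (patches grown by
#' seeded breadth-first search on the surface-residue adjacency graph) and
#' the p-value is the mid-p fraction of patches at least as hydrophobic.
#' Values below 0.5 indicate an interface more hydrophobic than a typical
#' surface patch. This is an analog of, not a reproduction of, the PISA
#' solvation free-energy p-value.
#'
#' @inheritParams buried_surface_area
#' @param n_resamples null patches to draw.
#' @param seed RNG seed.
#' @return p-value in (0, 1); attributes `score` (observed mean hydropathy)
#'   and `n_interface` (residue count).
#' @export
hydrophobicity_pvalue <- function(x, groupA, groupB, n_resamples = 1000L,
                                  seed = 1L, probe = 1.4, n_points = 240L) {
  rep_ <- buried_surface_area(x, groupA, groupB, probe = probe,
                              n_points = n_points)
  keys <- unlist(rep_$interface_residues, use.names = FALSE)
  if (length(keys) == 0L) stop("undefined statistic: interface is empty")
  tab <- residue_table(x)
  hyd <- function(idx) {
    h <- .kd_scale[tab$resname[idx]]
    mean(h[!is.na(h)])
  }
  obs <- hyd(match(keys, tab$key))
  # surface graph: residues with exposed area in the complex, adjacent when
  # their CA atoms are within 10 A
  full <- sasa(x, probe, n_points, include_het = FALSE)
  a2r <- atom2residue(x)
  res_area <- tapply(full$area[full$atoms], a2r[full$atoms], sum)
  surf <- as.integer(names(res_area))[res_area > 1]
  surf <- surf[!is.na(tab$ca[surf])]
  if (length(surf) < length(keys))
    stop("surface too small to resample patches of the interface size")
  xyz <- coords(x)[tab$ca[surf], , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  adj <- lapply(seq_along(surf), function(i) which(d[i, ] < 10 & seq_along(surf) != i))
  m <- length(keys)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  scores <- vapply(seq_len(n_resamples), function(k) {
    start <- sample.int(length(surf), 1L)
    patch <- start
    frontier <- adj[[start]]
    while (length(patch) < m && length(frontier) > 0) {
      nxt <- if (length(frontier) == 1L) frontier else
        sample(frontier, 1L)
      patch <- c(patch, nxt)
      frontier <- setdiff(unique(c(frontier, adj[[nxt]])), patch)
    }
    hyd(surf[patch])
  }, numeric(1))
  eps <- 1e-9
  p <- (sum(scores > obs + eps) + 0.5 * sum(abs(scores - obs) <= eps) + 0.5) /
    (n_resamples + 1)
  attr(p, "score") <- obs
  attr(p, "n_interface") <- m
  p
}
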