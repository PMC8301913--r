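# Shared fixture builders and independent oracles.

# minimal CA-only structure from an N x 3 coordinate matrix
mk_structure <- function(xyz, chain = "A", resid = seq_len(nrow(xyz)),
                         name = "CA", element = "C", resname = "ALA") {
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n), name = rep_len(name, n),
                      resname = rep_len(resname, n),
                      chain = rep_len(chain, n), resid = resid, inscode = "",
                      element = rep_len(element, n), occupancy = 1,
                      bfactor = 0, het = FALSE, stringsAsFactors = FALSE)
  structure3d(atoms, xyz)
}

# trajectory from a list of N x 3 frames
mk_trajectory <- function(topology, frame_list, dt = 0.1) {
  frames <- array(unlist(frame_list),
                  dim = c(nrow(frame_list[[1]]), 3L, length(frame_list)))
  trajectory3d(topology, frames, dt = dt)
}

# dynamical_network directly from a symmetric weight matrix (NA = no edge);
# bypasses the occupancy/correlation machinery for pure graph tests
mk_network <- function(W) {
  n <- nrow(W)
  tab <- data.frame(chain = "A", resid = seq_len(n), inscode = "",
                    resname = "ALA", key = paste0("A:", seq_len(n)),
                    ca = seq_len(n), stringsAsFactors = FALSE)
  idx <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], f = 1,
                      c = exp(-W[idx]), w = W[idx])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(residues = tab, edges = edges,
                 params = network_params(exclude_neighbors = 0L)),
            class = "dynamical_network")
}

rand_weight_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) W[i, j] <- W[j, i] <- runif(1, 0.1, 2)
  W
}

# ---- brute-force simple-path oracle -------------------------------------

enumerate_simple_paths <- function(W, s, t) {
  n <- nrow(W)
  out <- list()
  recurse <- function(path, weight) {
    u <- path[length(path)]
    if (u == t) {
      out[[length(out) + 1L]] <<- list(path = path, weight = weight)
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (!is.na(W[u, v]) && !(v %in% path))
        recurse(c(path, v), weight + W[u, v])
    }
  }
  recurse(s, 0)
  out
}

lex_before <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

# sort oracle paths by (weight, lexicographic), with weight tolerance eps
oracle_sort <- function(paths, eps = 1e-9) {
  if (length(paths) == 0) return(paths)
  ord <- seq_along(paths)
  cmp <- function(x, y) {
    if (paths[[x]]$weight < paths[[y]]$weight - eps) return(-1L)
    if (paths[[x]]$weight > paths[[y]]$weight + eps) return(1L)
    if (identical(paths[[x]]$path, paths[[y]]$path)) return(0L)
    if (lex_before(paths[[x]]$path, paths[[y]]$path)) -1L else 1L
  }
  # insertion sort (tiny inputs, custom comparator)
  for (i in seq_along(ord)[-1]) {
    k <- i
    while (k > 1 && cmp(ord[k], ord[k - 1]) < 0) {
      ord[c(k - 1, k)] <- ord[c(k, k - 1)]
      k <- k - 1
    }
  }
  paths[ord]
}

# ---- recovery fixture (central parameter-recovery conditions) -----------

recovery_model <- function() {
  toy <- make_toy_fold(32, "two_chain")
  path <- c("A:4", "A:6", "A:8", "B:8", "B:6")
  m <- elastic_model(toy, sigma = 0.5)
  m <- plant_correlated_path(m, path, rho = 0.9)
  cons <- cbind(path[-length(path)], path[-1])
  m <- plant_contact(m, cons, occupancy = 1.0)
  m <- plant_contact(m, rbind(c("A:4", "A:12"), c("A:12", "B:12"),
                              c("B:12", "B:6")), occupancy = 0.8)
  list(model = m, path = path, source = "A:4", sink = "B:6")
}

# raw (un-superposed) displacement correlation of two atoms — independent
# oracle for the trajectory generator
raw_correlation <- function(traj, i, j) {
  di <- t(traj$frames[i, , ]); dj <- t(traj$frames[j, , ])
  di <- sweep(di, 2L, colMeans(di)); dj <- sweep(dj, 2L, colMeans(dj))
  sum(di * dj) / sqrt(sum(di^2) * sum(dj^2))
}

# exact accessible area of two overlapping spheres (expanded radii R1, R2,
# centre distance d): each sphere loses a cap of height h_i
two_sphere_area <- function(R1, R2, d) {
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * max(h1, 0)) +
    (4 * pi * R2^2 - 2 * pi * R2 * max(h2, 0))
}

# two-residue toggling-contact trajectory (n_in frames at 4.0 A, n_out at 6.0 A)
two_res_top <- function() mk_structure(rbind(c(0, 0, 0), c(4, 0, 0)),
                                        chain = c("A", "B"), resid = c(1, 1))

toggling_traj <- function(n_in, n_out) {
  top <- two_res_top()
  frames <- c(replicate(n_in, rbind(c(0, 0, 0), c(4.0, 0, 0)),
                        simplify = FALSE),
              replicate(n_out, rbind(c(0, 0, 0), c(6.0, 0, 0)),
                        simplify = FALSE))
  mk_trajectory(top, frames)
}

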