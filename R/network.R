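#' Parameters of the dynamical network construction
#'
#' Residues become nodes anchored at their alpha carbons; an edge joins two
#' residues that stay within `contact_cutoff` of each other for at least
#' `occupancy_threshold` of the trajectory (inclusive), and carries weight
#' `-log(|C_ij|)` from the displacement cross-correlation.
#'
#' `contact_mode` decides which inter-residue distance the cutoff applies
#' to. The default is the minimum heavy-atom distance (the convention of the
#' dynamical-network methodology; a 4.5 A Calpha-Calpha requirement would
#' leave almost no contacts in real proteins). `"calpha"` applies the cutoff
#' to Calpha-Calpha distances, which is what Calpha-resolution synthetic
#' trajectories use.
#'
#' @param contact_cutoff contact distance cutoff, Angstrom (default 4.5).
#' @param occupancy_threshold minimum contact occupancy for an edge,
#'   fraction in (0, 1] (default 0.75, inclusive).
#' @param contact_mode `"heavy"` (min heavy-atom distance) or `"calpha"`.
#' @param exclude_neighbors sequence separation within a chain at or below
#'   which edges are suppressed (default 1: no i,i+1 backbone edges).
#' @return list of class `network_params`
#' @export
network_params <- function(contact_cutoff = 4.5, occupancy_threshold = 0.75,
                           contact_mode = c("heavy", "calpha"),
                           exclude_neighbors = 1L) {
  contact_mode <- match.arg(contact_mode)
  stopifnot(contact_cutoff > 0, occupancy_threshold > 0,
            occupancy_threshold <= 1, exclude_neighbors >= 0)
  out <- list(contact_cutoff = contact_cutoff,
              occupancy_threshold = occupancy_threshold,
              contact_mode = contact_mode,
              exclude_neighbors = as.integer(exclude_neighbors))
  class(out) <- "network_params"
  out
}

#' Contact occupancy map of a trajectory
#'
#' `f_ij` = fraction of frames in which residues i and j are within the
#' contact cutoff (minimum heavy-atom distance, or Calpha distance in
#' `"calpha"` mode).
#'
#' @param traj a [trajectory3d] with residue-resolved topology.
#' @param params a [network_params].
#' @return list of class `contact_occupancy`: `f` (R x R symmetric matrix of
#'   fractions, unit diagonal, residue keys as dimnames), `residues`
#'   (residue table), `params`.
#' @export
contact_occupancy <- function(traj, params = network_params()) {
  stopifnot(inherits(traj, "trajectory3d"), inherits(params, "network_params"))
  f <- n_frames(traj)
  if (f == 0L) stop("empty trajectory")
  tab <- residue_table(traj$topology)
  r <- nrow(tab)
  cnt <- matrix(0, r, r)
  if (params$contact_mode == "calpha") {
    if (anyNA(tab$ca))
      stop("calpha contact mode requires a CA atom in every residue")
    for (k in seq_len(f)) {
      d <- as.matrix(stats::dist(traj$frames[tab$ca, , k]))
      cnt <- cnt + (d <= params$contact_cutoff)
    }
  } else {
    a2r <- atom2residue(traj$topology)
    heavy <- which(traj$topology$atoms$element != "H")
    for (k in seq_len(f)) {
      d <- as.matrix(stats::dist(traj$frames[heavy, , k]))
      cnt <- cnt + residue_min_contact(d, a2r[heavy], r,
                                       params$contact_cutoff)
    }
  }
  occ <- cnt / f
  diag(occ) <- 1
  dimnames(occ) <- list(tab$key, tab$key)
  out <- list(f = occ, residues = tab, params = params)
  class(out) <- "contact_occupancy"
  out
}

# 0/1 matrix of residue pairs whose minimum atom distance is <= cutoff
residue_min_contact <- function(d, grp, r, cutoff) {
  hit <- which(d <= cutoff, arr.ind = TRUE)
  gi <- grp[hit[, 1]]; gj <- grp[hit[, 2]]
  out <- matrix(0, r, r)
  out[cbind(gi, gj)] <- 1
  out
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Normalised scalar cross-correlations of Calpha displacement vectors,
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, after superposing all
#' frames onto the iterated mean structure (two passes) over the selection.
#'
#' Note that the rigid-body fit interacts with the correlations it
#' measures: on small systems, removing the best-fit rotation/translation
#' absorbs part of the motion of any strongly correlated block and biases
#' its correlations downward (a known property of DCCMs, vanishing as the
#' system grows). `fit = FALSE` skips the superposition for trajectories
#' already expressed in a common frame.
#'
#' @param traj a [trajectory3d], F >= 2.
#' @param selection atom indices over which to compute (default: one Calpha
#'   per residue, in residue-table order).
#' @param fit superpose frames to the iterated mean first (default TRUE).
#' @return list of class `dccm_matrix`: `C` (R x R, unit diagonal, residue
#'   keys as dimnames when the default selection is used), `residues`.
#' @export
cross_correlation <- function(traj, selection = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (n_frames(traj) < 2L)
    stop("cross-correlation needs at least 2 frames")
  tab <- residue_table(traj$topology)
  if (is.null(selection)) {
    if (anyNA(tab$ca)) stop("default selection requires a CA per residue")
    selection <- tab$ca
    keys <- tab$key
  } else {
    keys <- with(traj$topology$atoms[selection, ],
                 paste0(chain, ":", resid, ".", name))
  }
  sub <- traj$frames[selection, , , drop = FALSE]
  if (fit) {
    fitres <- iterated_mean_fit(sub, seq_along(selection), iterations = 2L)
  } else {
    fitres <- list(frames = sub, mean = apply(sub, c(1L, 2L), mean))
  }
  dev <- sweep(fitres$frames, c(1L, 2L), fitres$mean)
  f <- dim(dev)[3]
  num <- matrix(0, length(selection), length(selection))
  for (a in 1:3) {
    da <- dev[, a, , drop = FALSE]; dim(da) <- c(length(selection), f)
    num <- num + tcrossprod(da)
  }
  v <- diag(num)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero))
    stop("undefined correlation: zero displacement variance for residue(s) ",
         paste(keys[zero], collapse = ", "))
  C <- num / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  dimnames(C) <- list(keys, keys)
  out <- list(C = C, residues = tab)
  class(out) <- "dccm_matrix"
  out
}

#' Build a dynamical residue-interaction network
#'
#' Edge set: residue pairs with contact occupancy `f_ij >=
#' occupancy_threshold` (inclusive) whose sequence separation exceeds
#' `exclude_neighbors` (pairs on different chains always qualify). Edge
#' weight: `w_ij = -log(|C_ij|)`, so perfectly correlated contacts cost 0
#' and uncorrelated ones are expensive. Edges whose correlation is exactly
#' zero would carry infinite weight and are dropped with a warning.
#'
#' @param occ a [contact_occupancy].
#' @param corr a [cross_correlation] result (`dccm_matrix`) with the same
#'   residue indexing, or a bare R x R matrix.
#' @param params a [network_params]; defaults to the parameters stored in
#'   `occ`.
#' @param weights `"correlation"` (default, `-log|C|`) or `"uniform"` (every
#'   edge weight 1: optimal paths then minimise hop count).
#' @return list of class `dynamical_network`: `residues`, `edges`
#'   (data.frame `i, j, f, c, w` with i < j as residue indices), `params`.
#' @export
build_network <- function(occ, corr, params = occ$params,
                          weights = c("correlation", "uniform")) {
  stopifnot(inherits(occ, "contact_occupancy"))
  weights <- match.arg(weights)
  C <- if (inherits(corr, "dccm_matrix")) corr$C else as.matrix(corr)
  if (!all(dim(C) == dim(occ$f)))
    stop("occupancy and correlation matrices index different residue sets")
  tab <- occ$residues
  r <- nrow(tab)
  thr <- params$occupancy_threshold - 1e-12     # inclusive >= at f == threshold
  pairs <- which(upper.tri(occ$f) & occ$f >= thr, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    same_chain <- tab$chain[pairs[, 1]] == tab$chain[pairs[, 2]]
    sep <- abs(tab$resid[pairs[, 1]] - tab$resid[pairs[, 2]])
    keep <- !same_chain | sep > params$exclude_neighbors
    pairs <- pairs[keep, , drop = FALSE]
  }
  cij <- C[pairs]
  if (weights == "correlation") {
    zero <- abs(cij) == 0
    if (any(zero)) {
      warning(sum(zero), " edge(s) with zero correlation dropped ",
              "(infinite weight)")
      pairs <- pairs[!zero, , drop = FALSE]
      cij <- cij[!zero]
    }
    w <- -log(abs(cij))
  } else {
    w <- rep(1, length(cij))
  }
  edges <- data.frame(i = pairs[, 1], j = pairs[, 2],
                      f = occ$f[pairs], c = cij, w = w)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  out <- list(residues = tab, edges = edges, params = params)
  class(out) <- "dynamical_network"
  out
}

#' @export
print.dynamical_network <- function(x, ...) {
  cat(sprintf("dynamical_network: %d nodes, %d edges (cutoff %.1f A, occupancy >= %.2f, %s contacts)\n",
              nrow(x$residues), nrow(x$edges), x$params$contact_cutoff,
              x$params$occupancy_threshold, x$params$contact_mode))
  invisible(x)
}

# adjacency list: for each node, data.frame(nb, w)
adjacency_list <- function(net) {
  r <- nrow(net$residues)
  adj <- vector("list", r)
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    adj[[e$i[k]]] <- rbind(adj[[e$i[k]]], c(e$j[k], e$w[k]))
    adj[[e$j[k]]] <- rbind(adj[[e$j[k]]], c(e$i[k], e$w[k]))
  }
  lapply(adj, function(m) {
    if (is.null(m)) return(matrix(numeric(), 0, 2))
    m[order(m[, 1]), , drop = FALSE]
  })
}

# lexicographic comparison of integer vectors: -1, 0, 1
lex_cmp <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  sign(length(a) - length(b))
}

# (weight, path) comparator with tolerance on weight
path_less <- function(wa, pa, wb, pb, eps = 1e-9) {
  if (wa < wb - eps) return(TRUE)
  if (wa > wb + eps) return(FALSE)
  lex_cmp(pa, pb) < 0
}

# Dijkstra with lexicographic tie-break on the node sequence. `blocked`
# nodes and `blocked_edges` (2-col matrix, undirected) are ignored; used by
# the suboptimal-path search. Returns list(path, weight) or NULL.
dijkstra_lex <- function(adj, source, sink, blocked = integer(),
                         blocked_edges = NULL) {
  r <- length(adj)
  dist <- rep(Inf, r)
  paths <- vector("list", r)
  done <- rep(FALSE, r)
  done[blocked] <- TRUE
  dist[source] <- 0
  paths[[source]] <- source
  edge_blocked <- function(u, v) {
    !is.null(blocked_edges) &&
      any((blocked_edges[, 1] == u & blocked_edges[, 2] == v) |
          (blocked_edges[, 1] == v & blocked_edges[, 2] == u))
  }
  repeat {
    u <- 0L; bw <- Inf; bp <- NULL
    for (k in which(!done & is.finite(dist))) {
      if (u == 0L || path_less(dist[k], paths[[k]], bw, bp)) {
        u <- k; bw <- dist[k]; bp <- paths[[k]]
      }
    }
    if (u == 0L) return(NULL)
    if (u == sink) return(list(path = paths[[u]], weight = dist[u]))
    done[u] <- TRUE
    nb <- adj[[u]]
    for (k in seq_len(nrow(nb))) {
      v <- as.integer(nb[k, 1]); w <- nb[k, 2]
      if (done[v] || edge_blocked(u, v)) next
      nd <- dist[u] + w
      np <- c(paths[[u]], v)
      if (!is.finite(dist[v]) || path_less(nd, np, dist[v], paths[[v]])) {
        dist[v] <- nd
        paths[[v]] <- np
      }
    }
  }
}

# connected component labels of the network graph
graph_components <- function(net) {
  r <- nrow(net$residues)
  adj <- adjacency_list(net)
  comp <- rep(NA_integer_, r)
  cur <- 0L
  for (s in seq_len(r)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      nb <- as.integer(adj[[u]][, 1])
      new <- nb[is.na(comp[nb])]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

resolve_node <- function(net, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > nrow(net$residues)) stop("node index out of range")
    return(node)
  }
  idx <- match(node, net$residues$key)
  if (is.na(idx)) stop("node not found in network: ", node)
  idx
}

#' Optimal (shortest-weight) path between two residues
#'
#' The optimal path is the source-to-sink path with the smallest sum of edge
#' weights. Among equal-weight optima the lexicographically smallest node
#' sequence is returned, so results are reproducible.
#'
#' @param net a [build_network] result.
#' @param source,sink residue index or `"chain:resid"` key; must differ and
#'   lie in the same connected component.
#' @return list of class `network_path`: `path` (residue indices), `keys`,
#'   `weight`.
#' @export
optimal_path <- function(net, source, sink) {
  stopifnot(inherits(net, "dynamical_network"))
  s <- resolve_node(net, source); t <- resolve_node(net, sink)
  if (s == t) stop("source and sink must differ")
  res <- dijkstra_lex(adjacency_list(net), s, t)
  if (is.null(res)) {
    comp <- graph_components(net)
    stop(sprintf(
      "no path: source and sink in different components (sizes %d and %d)",
      sum(comp == comp[s]), sum(comp == comp[t])))
  }
  out <- list(path = res$path, keys = net$residues$key[res$path],
              weight = res$weight)
  class(out) <- "network_path"
  out
}

#' @export
print.network_path <- function(x, ...) {
  cat(sprintf("path (weight %.4f): %s\n", x$weight,
              paste(x$keys, collapse = " - ")))
  invisible(x)
}

#' Optimal and suboptimal paths between two residues
#'
#' Enumerates, by a Yen-style k-shortest simple path search, every simple
#' path whose total weight is within `tolerance` of the optimal path weight
#' (up to `max_paths`), sorted by ascending weight with lexicographic
#' tie-breaking. Node usage frequencies over the ensemble flag residues
#' important for allosteric communication between the endpoints.
#'
#' @inheritParams optimal_path
#' @param tolerance non-negative weight allowance above the optimum
#'   (tolerance 0 returns optimal paths only).
#' @param max_paths cap on the number of returned paths (default 500).
#' @return list of class `path_ensemble`: `paths` (list of index vectors),
#'   `weights`, `node_frequency` (named count vector over all residues),
#'   `source`, `sink`, `tolerance`, `residues`.
#' @export
suboptimal_paths <- function(net, source, sink, tolerance = 20,
                             max_paths = 500L) {
  stopifnot(inherits(net, "dynamical_network"))
  if (tolerance < 0) stop("tolerance must be non-negative")
  s <- resolve_node(net, source); t <- resolve_node(net, sink)
  if (s == t) stop("source and sink must differ")
  adj <- adjacency_list(net)
  best <- dijkstra_lex(adj, s, t)
  if (is.null(best)) {
    comp <- graph_components(net)
    stop(sprintf(
      "no path: source and sink in different components (sizes %d and %d)",
      sum(comp == comp[s]), sum(comp == comp[t])))
  }
  bound <- best$weight + tolerance + 1e-9
  A <- list(best)
  B <- list()
  while (length(A) < max_paths) {
    prev <- A[[length(A)]]$path
    for (sp in seq_len(length(prev) - 1L)) {
      root <- prev[seq_len(sp)]
      spur <- prev[sp]
      bl_edges <- NULL
      for (p in c(A, B)) {
        pp <- p$path
        if (length(pp) > sp && identical(pp[seq_len(sp)], root))
          bl_edges <- rbind(bl_edges, c(spur, pp[sp + 1L]))
      }
      blocked <- setdiff(root, spur)
      res <- dijkstra_lex(adj, spur, t, blocked = blocked,
                          blocked_edges = bl_edges)
      if (is.null(res)) next
      rootw <- if (sp > 1L)
        sum(vapply(seq_len(sp - 1L), function(k) {
          nb <- adj[[prev[k]]]
          nb[match(prev[k + 1L], nb[, 1]), 2]
        }, numeric(1))) else 0
      cand <- list(path = c(root[-sp], res$path), weight = rootw + res$weight)
      if (cand$weight > bound) next
      dup <- any(vapply(c(A, B), function(p) identical(p$path, cand$path),
                        logical(1)))
      if (!dup) B <- c(B, list(cand))
    }
    if (length(B) == 0L) break
    pick <- 1L
    for (k in seq_along(B))
      if (path_less(B[[k]]$weight, B[[k]]$path,
                    B[[pick]]$weight, B[[pick]]$path)) pick <- k
    nxt <- B[[pick]]
    B <- B[-pick]
    if (nxt$weight > bound) break
    A <- c(A, list(nxt))
  }
  weights <- vapply(A, `[[`, numeric(1), "weight")
  keep <- weights <= bound
  A <- A[keep]; weights <- weights[keep]
  freq <- integer(nrow(net$residues))
  names(freq) <- net$residues$key
  for (p in A) freq[p$path] <- freq[p$path] + 1L
  out <- list(paths = lapply(A, `[[`, "path"), weights = weights,
              node_frequency = freq, source = s, sink = t,
              tolerance = tolerance, residues = net$residues)
  class(out) <- "path_ensemble"
  out
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("path_ensemble: %d path(s), weights %.4f-%.4f, tolerance %g\n",
              length(x$paths), min(x$weights), max(x$weights), x$tolerance))
  invisible(x)
}

#' Partition trajectory frames into contiguous windows
#'
#' @param n_frames total frame count.
#' @param n_windows number of contiguous, non-overlapping windows covering
#'   all frames (sizes differ by at most one frame when not divisible).
#' @return list of class `window_scheme`; element k is the integer frame
#'   range of window k.
#' @export
window_scheme <- function(n_frames, n_windows) {
  stopifnot(n_windows >= 1L, n_frames >= n_windows)
  sizes <- rep(n_frames %/% n_windows, n_windows)
  extra <- n_frames %% n_windows
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  out <- lapply(seq_len(n_windows),
                function(k) (c(0L, ends)[k] + 1L):ends[k])
  class(out) <- "window_scheme"
  out
}

#' Windowed (segmented) network analysis
#'
#' Splits the trajectory into contiguous windows (e.g., seven 50-ns segments
#' of a 350-ns run) and runs the full analysis — contact occupancy, DCCM,
#' network build, and optionally path search — independently on each
#' window, preserving window order. With one window this reproduces the
#' full-trajectory analysis exactly.
#'
#' @param traj a [trajectory3d].
#' @param scheme a [window_scheme] or an integer number of windows.
#' @param params a [network_params].
#' @param source,sink optional path endpoints; when given, each window also
#'   carries a [suboptimal_paths] ensemble.
#' @param tolerance,max_paths passed to [suboptimal_paths].
#' @return list of per-window lists with elements `frames` (range),
#'   `network`, and (when endpoints are given) `paths`.
#' @export
windowed_networks <- function(traj, scheme, params = network_params(),
                              source = NULL, sink = NULL, tolerance = 20,
                              max_paths = 500L) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (is.numeric(scheme)) scheme <- window_scheme(n_frames(traj), scheme)
  idx <- sort(unlist(scheme))
  if (!identical(idx, seq_len(n_frames(traj))))
    stop("window scheme must partition the frame range")
  lapply(scheme, function(rng) {
    if (length(rng) < 2L)
      stop("window of ", length(rng), " frame(s): need at least 2")
    sub <- trajectory3d(traj$topology,
                        traj$frames[, , rng, drop = FALSE], dt = traj$dt)
    net <- build_network(contact_occupancy(sub, params),
                         cross_correlation(sub), params)
    out <- list(frames = range(rng), network = net)
    if (!is.null(source) && !is.null(sink))
      out$paths <- suboptimal_paths(net, source, sink, tolerance = tolerance,
                                    max_paths = max_paths)
    out
  })
}

#' Cross-interface edge summary
#'
#' Lists every network edge whose endpoints fall in different groups of a
#' chain-to-group assignment (e.g., the Ras-Ras', Ras-Raf-CRD' and
#' Ras-Raf-RBD_CRD interfaces of a two-protomer complex), with occupancy,
#' correlation and weight per edge.
#'
#' @param net a `dynamical_network`.
#' @param groups named character vector mapping every chain to a group
#'   label.
#' @return data.frame with columns `node_i`, `node_j`, `group_i`, `group_j`,
#'   `f`, `c`, `w`, ordered as in the edge table.
#' @export
interface_edge_summary <- function(net, groups) {
  stopifnot(inherits(net, "dynamical_network"))
  chains <- unique(net$residues$chain)
  missing <- setdiff(chains, names(groups))
  if (length(missing) > 0)
    stop("chain(s) without group assignment: ",
         paste(missing, collapse = ", "))
  gi <- groups[net$residues$chain[net$edges$i]]
  gj <- groups[net$residues$chain[net$edges$j]]
  cross <- gi != gj
  data.frame(node_i = net$residues$key[net$edges$i[cross]],
             node_j = net$residues$key[net$edges$j[cross]],
             group_i = unname(gi[cross]), group_j = unname(gj[cross]),
             f = net$edges$f[cross], c = net$edges$c[cross],
             w = net$edges$w[cross], stringsAsFactors = FALSE)
}

#' Export a network edge list as TSV
#'
#' Writes `node_i, node_j, f_ij, C_ij, w_ij` with a commented header line
#' recording the construction parameters.
#'
#' @param net a `dynamical_network`.
#' @param path output file.
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "dynamical_network"))
  hdr <- sprintf("# cutoff=%g A, occupancy>=%g, mode=%s, exclude_neighbors=%d",
                 net$params$contact_cutoff, net$params$occupancy_threshold,
                 net$params$contact_mode, net$params$exclude_neighbors)
  df <- data.frame(node_i = net$residues$key[net$edges$i],
                   node_j = net$residues$key[net$edges$j],
                   f_ij = net$edges$f, C_ij = net$edges$c, w_ij = net$edges$w)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
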