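test_that("contact occupancy uses an inclusive threshold at exactly 75%", {
  p <- network_params(contact_mode = "calpha")

  occ6of8 <- contact_occupancy(toggling_traj(6, 2), p)
  expect_equal(occ6of8$f[1, 2], 0.75)
  net <- build_network(occ6of8, matrix(c(1, .5, .5, 1), 2), p)
  expect_equal(nrow(net$edges), 1L)          # retained at the boundary

  occ74 <- contact_occupancy(toggling_traj(74, 26), p)
  expect_equal(occ74$f[1, 2], 0.74)
  net74 <- build_network(occ74, matrix(c(1, .5, .5, 1), 2), p)
  expect_equal(nrow(net74$edges), 0L)        # 74% misses the cutoff

  occ0 <- contact_occupancy(toggling_traj(0, 10), p)
  expect_equal(occ0$f[1, 2], 0)
})

test_that("planted occupancy is recovered within its binomial interval", {
  toy <- make_toy_fold(12, "two_chain")
  m <- plant_contact(elastic_model(toy, 0.3), c("A:3", "B:3"), 0.9)
  tr <- sample_trajectory(m, 2000, seed = 17)
  occ <- contact_occupancy(tr, network_params(contact_mode = "calpha"))
  f <- occ$f["A:3", "B:3"]
  expect_gte(f, 0.87); expect_lte(f, 0.93)
})

test_that("the DCCM has unit diagonal and detects identical motion", {
  toy <- make_toy_fold(6, "chain")
  set.seed(3)
  base <- coords(toy)
  frames <- lapply(1:40, function(k) {
    d <- matrix(rnorm(18, sd = 0.3), 6, 3)
    d[2, ] <- d[1, ]              # residues 1 and 2 move in lockstep
    base + d
  })
  # fit = FALSE isolates the correlation formula itself: a rigid-body fit
  # would re-rotate frames and break the planted displacement identity
  cc <- cross_correlation(mk_trajectory(toy, frames), fit = FALSE)
  expect_equal(diag(cc$C), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cc$C[1, 2], 1, tolerance = 1e-12)
  expect_true(isSymmetric(cc$C))
  expect_true(all(abs(cc$C) <= 1 + 1e-12))
  # with the fit the property still holds to a few percent on this system
  ccf <- cross_correlation(mk_trajectory(toy, frames))
  expect_gt(ccf$C[1, 2], 0.85)
})

test_that("planted correlations appear in the DCCM within tolerance", {
  # N chosen large enough that the rigid-body fit bias is inside the band
  toy <- make_toy_fold(100, "helix")
  m <- plant_correlated_path(elastic_model(toy, 0.5), c(5, 8, 11), rho = 0.9)
  tr <- sample_trajectory(m, 5000, seed = 23)
  cc <- cross_correlation(tr)
  expect_equal(cc$C[5, 8], 0.9, tolerance = 0.056)   # |C - 0.9| <= 0.05
  expect_equal(cc$C[8, 11], 0.9, tolerance = 0.056)
})

test_that("the DCCM agrees with an established implementation", {
  toy <- make_toy_fold(15, "helix")
  tr <- sample_trajectory(
    plant_correlated_path(elastic_model(toy, 0.5), 2:4, 0.8), 200, seed = 9)
  cc <- cross_correlation(tr)
  # bio3d::dccm on the same fitted coordinates is the independent route
  fit <- netdyn:::iterated_mean_fit(tr$frames, 1:15, iterations = 2L)
  xyz <- t(apply(fit$frames, 3L, function(m) as.vector(t(m))))
  ref <- suppressMessages(bio3d::dccm.xyz(xyz))
  expect_equal(unname(cc$C), unname(ref[, ]), tolerance = 1e-6)
})

test_that("zero-variance residues are reported by name", {
  toy <- make_toy_fold(5, "helix")
  const <- mk_trajectory(toy, replicate(3, coords(toy), simplify = FALSE))
  expect_error(cross_correlation(const), "zero displacement variance")
})

test_that("edge weights follow -log|C| and threshold exclusivity", {
  p <- network_params(contact_mode = "calpha")
  occ <- contact_occupancy(toggling_traj(10, 0), p)
  C1 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(build_network(occ, C1, p)$edges$w, 0)
  C5 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(build_network(occ, C5, p)$edges$w, log(2))
  C0 <- matrix(c(1, 0, 0, 1), 2)
  expect_warning(net0 <- build_network(occ, C0, p), "zero correlation")
  expect_equal(nrow(net0$edges), 0L)
})

test_that("sequence neighbours are excluded but cross-chain pairs are not", {
  toy <- make_toy_fold(6, "chain")     # consecutive CA at 3.8 A
  tr <- mk_trajectory(toy, replicate(4, coords(toy), simplify = FALSE))
  occ <- contact_occupancy(tr, network_params(contact_mode = "calpha"))
  expect_true(all(diag(occ$f[-1, ]) == 1))   # i,i+1 in permanent contact
  C <- diag(6) * 0.5 + 0.5
  net <- build_network(occ, C, network_params(contact_mode = "calpha"))
  expect_equal(nrow(net$edges), 0L)          # all contacts are i,i+1
  net0 <- build_network(occ, C, network_params(contact_mode = "calpha",
                                               exclude_neighbors = 0L))
  expect_equal(nrow(net0$edges), 5L)
})

test_that("raising the occupancy threshold never adds edges", {
  rec <- recovery_model()
  tr <- sample_trajectory(rec$model, 400, seed = 77)
  base_p <- network_params(contact_mode = "calpha",
                           occupancy_threshold = 0.55)
  occ <- contact_occupancy(tr, base_p)
  C <- cross_correlation(tr)
  prev <- NULL
  for (thr in c(0.55, 0.65, 0.75, 0.85, 0.95)) {
    p <- network_params(contact_mode = "calpha", occupancy_threshold = thr)
    e <- build_network(occ, C, p)$edges
    key <- paste(e$i, e$j)
    if (!is.null(prev)) expect_true(all(key %in% prev))
    prev <- key
  }
})

test_that("optimal paths match trivial closed forms", {
  W <- matrix(NA_real_, 2, 2); W[1, 2] <- W[2, 1] <- 0.3
  net <- mk_network(W)
  op <- optimal_path(net, 1, 2)
  expect_equal(op$path, c(1L, 2L))
  expect_equal(op$weight, 0.3)

  # 3x3 grid with equal weights, opposite corners: 4 edges, lexicographic
  # smallest of the equal-weight optima
  W <- matrix(NA_real_, 9, 9)
  for (i in 1:3) for (j in 1:3) {
    id <- (i - 1) * 3 + j
    if (j < 3) W[id, id + 1] <- W[id + 1, id] <- 0.25
    if (i < 3) W[id, id + 3] <- W[id + 3, id] <- 0.25
  }
  op <- optimal_path(mk_network(W), 1, 9)
  expect_equal(op$weight, 1.0)
  expect_equal(op$path, c(1L, 2L, 3L, 6L, 9L))
})

test_that("optimal and suboptimal paths equal brute-force enumeration", {
  hits <- 0L
  for (seed in 1:100) {
    n <- 4L + (seed %% 5L)               # 4..8 nodes
    W <- rand_weight_graph(n, p = 0.55, seed = seed)
    net <- mk_network(W)
    oracle <- enumerate_simple_paths(W, 1L, n)
    if (length(oracle) == 0L) {
      expect_error(optimal_path(net, 1, n), "no path")
      next
    }
    oracle <- oracle_sort(oracle)
    op <- optimal_path(net, 1, n)
    expect_equal(op$weight, oracle[[1]]$weight, tolerance = 1e-9)
    expect_identical(op$path, as.integer(oracle[[1]]$path))

    tol <- 1.0
    bound <- oracle[[1]]$weight + tol + 1e-9
    want <- Filter(function(p) p$weight <= bound, oracle)
    got <- suboptimal_paths(net, 1, n, tolerance = tol, max_paths = 1000L)
    expect_equal(length(got$paths), length(want))
    for (k in seq_along(want)) {
      expect_identical(got$paths[[k]], as.integer(want[[k]]$path))
      expect_equal(got$weights[k], want[[k]]$weight, tolerance = 1e-9)
    }
    hits <- hits + 1L
  }
  expect_gte(hits, 50L)   # most random graphs connect source and sink
})

test_that("optimal weights agree with igraph shortest paths", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 14, 62)) {
    W <- rand_weight_graph(7, p = 0.6, seed = seed)
    net <- mk_network(W)
    e <- net$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$i, to = e$j, weight = e$w), directed = FALSE,
      vertices = data.frame(name = 1:7))
    dmat <- igraph::distances(g, v = "1", to = "7")
    if (is.infinite(dmat[1, 1])) {
      expect_error(optimal_path(net, 1, 7), "no path")
    } else {
      expect_equal(optimal_path(net, 1, 7)$weight, dmat[1, 1],
                   tolerance = 1e-9)
    }
  }
})

test_that("suboptimal ensembles are sorted, bounded and well-counted", {
  W <- matrix(NA_real_, 6, 6)
  edges <- rbind(c(1, 2, .2), c(2, 3, .2), c(3, 6, .2), c(1, 4, .5),
                 c(4, 5, .5), c(5, 6, .5), c(2, 5, .4), c(1, 6, 2.0))
  for (k in seq_len(nrow(edges)))
    W[edges[k, 1], edges[k, 2]] <- W[edges[k, 2], edges[k, 1]] <- edges[k, 3]
  net <- mk_network(W)

  only <- suboptimal_paths(net, 1, 6, tolerance = 0)
  expect_equal(length(only$paths), 1L)
  expect_identical(only$paths[[1]], optimal_path(net, 1, 6)$path)

  ens <- suboptimal_paths(net, 1, 6, tolerance = 2.0)
  expect_true(all(diff(ens$weights) >= -1e-12))
  expect_true(all(ens$weights <= ens$weights[1] + 2.0 + 1e-9))
  npaths <- length(ens$paths)
  expect_equal(unname(ens$node_frequency[c(1, 6)]), rep(npaths, 2))
  expect_true(all(vapply(ens$paths, function(p) !anyDuplicated(p),
                         logical(1))))
  expect_error(suboptimal_paths(net, 1, 6, tolerance = -1), "non-negative")
})

test_that("removing an edge off every returned path leaves the ensemble unchanged", {
  W <- matrix(NA_real_, 6, 6)
  edges <- rbind(c(1, 2, .2), c(2, 3, .2), c(3, 6, .2), c(1, 4, 3),
                 c(4, 5, 3), c(5, 6, 3), c(4, 2, 3))
  for (k in seq_len(nrow(edges)))
    W[edges[k, 1], edges[k, 2]] <- W[edges[k, 2], edges[k, 1]] <- edges[k, 3]
  ens <- suboptimal_paths(mk_network(W), 1, 6, tolerance = 1.0)
  used <- unique(unlist(lapply(ens$paths, function(p)
    paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1])))))
  expect_false("4 5" %in% used)
  W2 <- W; W2[4, 5] <- W2[5, 4] <- NA
  ens2 <- suboptimal_paths(mk_network(W2), 1, 6, tolerance = 1.0)
  expect_identical(ens$paths, ens2$paths)
  expect_equal(ens$weights, ens2$weights)
})

test_that("disconnected endpoints report component sizes", {
  W <- matrix(NA_real_, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5; W[4, 5] <- W[5, 4] <- 0.5
  expect_error(optimal_path(mk_network(W), 1, 5), "sizes 2 and 3")
})

test_that("the planted allosteric path is recovered end to end", {
  rec <- recovery_model()
  tr <- sample_trajectory(rec$model, 5000, seed = 1)
  p <- network_params(contact_mode = "calpha")
  net <- build_network(contact_occupancy(tr, p), cross_correlation(tr), p)
  op <- optimal_path(net, rec$source, rec$sink)
  expect_identical(op$keys, rec$path)
  # suboptimal ensemble ranks the planted path first
  ens <- suboptimal_paths(net, rec$source, rec$sink, tolerance = 0.5)
  expect_identical(ens$paths[[1]], op$path)
})

test_that("windowing partitions frames and reduces to the full analysis", {
  sizes <- vapply(window_scheme(3500, 7), length, integer(1))
  expect_equal(sizes, rep(500L, 7))
  expect_equal(sort(unlist(window_scheme(10, 3))), 1:10)

  rec <- recovery_model()
  tr <- sample_trajectory(rec$model, 300, seed = 5)
  p <- network_params(contact_mode = "calpha")
  full <- build_network(contact_occupancy(tr, p), cross_correlation(tr), p)
  win1 <- windowed_networks(tr, 1, p)
  expect_identical(win1[[1]]$network$edges, full$edges)

  bad <- window_scheme(299, 2)
  expect_error(windowed_networks(tr, bad, p), "partition")
})

test_that("windows of a stationary generator agree on the optimal path", {
  rec <- recovery_model()
  tr <- sample_trajectory(rec$model, 1500, seed = 2)
  p <- network_params(contact_mode = "calpha")
  wins <- windowed_networks(tr, 3, p, source = rec$source, sink = rec$sink,
                            tolerance = 0)
  for (w in wins)
    expect_identical(w$network$residues$key[w$paths$paths[[1]]], rec$path)
})

test_that("window shorter than two frames is rejected", {
  toy <- make_toy_fold(6, "chain")
  tr <- sample_trajectory(elastic_model(toy, 0.3), 3, seed = 1)
  expect_error(
    windowed_networks(tr, window_scheme(3, 3),
                      network_params(contact_mode = "calpha")),
    "at least 2")
})

test_that("interface edge summaries list exactly the cross-group edges", {
  rec <- recovery_model()
  tr <- sample_trajectory(rec$model, 1000, seed = 3)
  p <- network_params(contact_mode = "calpha")
  net <- build_network(contact_occupancy(tr, p), cross_correlation(tr), p)

  expect_error(interface_edge_summary(net, c(A = "g1")), "without group")
  one <- interface_edge_summary(net, c(A = "g1", B = "g1"))
  expect_equal(nrow(one), 0L)

  tab <- interface_edge_summary(net, c(A = "ras", B = "raf"))
  cross <- net$residues$chain[net$edges$i] != net$residues$chain[net$edges$j]
  expect_equal(nrow(tab), sum(cross))
  # weights recomputed independently from the correlation column
  expect_equal(tab$w, -log(abs(tab$c)), tolerance = 1e-12)
})

test_that("edge lists round-trip through the TSV export", {
  rec <- recovery_model()
  tr <- sample_trajectory(rec$model, 500, seed = 4)
  p <- network_params(contact_mode = "calpha")
  net <- build_network(contact_occupancy(tr, p), cross_correlation(tr), p)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$w_ij, net$edges$w, tolerance = 1e-12)
})
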