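test_that("kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)

  sp0 <- kabsch_superpose(P, P)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-8)

  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(R90), 2L, c(1, 2, 3), `+`)
  sp <- kabsch_superpose(Q, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_superposition(Q, sp), P, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch rmsd matches a brute-force rotational minimiser", {
  set.seed(7)
  A <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 1, 1, 2), 4, 3, byrow = TRUE)
  B <- A + matrix(rnorm(12, sd = 0.3), 4, 3)
  got <- kabsch_superpose(A, B)$rmsd

  # oracle: centre both, scan Euler angles on a coarse grid, refine by optim
  Ac <- sweep(A, 2L, colMeans(A)); Bc <- sweep(B, 2L, colMeans(B))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(ang) sqrt(mean(rowSums((Ac %*% t(rotmat(ang)) - Bc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, by = pi / 6),
                      b = seq(0, pi, by = pi / 6),
                      c = seq(0, 2 * pi, by = pi / 6))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  oracle <- stats::optim(start, obj)$value
  expect_equal(got, oracle, tolerance = 1e-4)
  expect_lte(got, oracle + 1e-8)
})

test_that("kabsch agrees with an established rigid-fit implementation", {
  set.seed(2)
  A <- matrix(rnorm(45), 15, 3)
  B <- A + matrix(rnorm(45, sd = 0.4), 15, 3)
  got <- kabsch_superpose(A, B)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)),
                   mobile = matrix(as.vector(t(A)), nrow = 1)))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(got, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd series is zero for identical and rigidly moved frames", {
  toy <- make_toy_fold(10, "helix")
  frames <- replicate(4, coords(toy), simplify = FALSE)
  tr <- mk_trajectory(toy, frames)
  expect_equal(rmsd_series(tr, toy), rep(0, 4), tolerance = 1e-10)

  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- lapply(1:4, function(k)
    sweep(coords(toy) %*% t(R), 2L, c(k, -k, 2 * k), `+`))
  tr2 <- mk_trajectory(toy, moved)
  expect_equal(rmsd_series(tr2, toy), rep(0, 4), tolerance = 1e-8)
})

test_that("rmsd under isotropic noise matches its closed form", {
  # superposition absorbs ~6 dof: E[RMSD] ~ sqrt(3)*sigma*sqrt((N-3.5)/N)
  n <- 50; sigma <- 0.5
  toy <- make_toy_fold(n, "helix")
  tr <- sample_trajectory(elastic_model(toy, sigma), 3000, seed = 21)
  expected <- sqrt(3) * sigma * sqrt((n - 3.5) / n)
  expect_equal(mean(rmsd_series(tr, toy)), expected, tolerance = 0.05)
})

test_that("rmsf is zero for a constant trajectory and needs 2 frames", {
  toy <- make_toy_fold(8, "helix")
  tr <- mk_trajectory(toy, replicate(3, coords(toy), simplify = FALSE))
  expect_equal(rmsf(tr)$rmsf, rep(0, 8), tolerance = 1e-12)
  tr1 <- mk_trajectory(toy, list(coords(toy)))
  expect_error(rmsf(tr1), "at least 2")
})

test_that("rmsf under isotropic noise matches sqrt(3)*sigma", {
  toy <- make_toy_fold(100, "helix")
  tr <- sample_trajectory(elastic_model(toy, 0.5), 4000, seed = 31)
  fp <- rmsf(tr)
  expect_equal(mean(fp$rmsf), sqrt(3) * 0.5, tolerance = 0.05)
})

test_that("a floppy domain shows larger rmsf than a stiff core", {
  toy <- make_toy_fold(40, "helix")
  sigma <- c(rep(0.3, 30), rep(0.9, 10))   # stiff core, floppy tail
  tr <- sample_trajectory(elastic_model(toy, sigma), 2000, seed = 41)
  fp <- rmsf(tr)
  expect_gt(mean(fp$rmsf[31:40]), mean(fp$rmsf[1:30]))
})

test_that("distance series follow exact geometry", {
  top <- mk_structure(rbind(c(0, 0, 0), c(3, 4, 0)),
                      chain = c("A", "B"), resid = c(1, 1))
  tr <- mk_trajectory(top, replicate(5, coords(top), simplify = FALSE))
  expect_equal(distance_series(tr, 1, 2), rep(5, 5))
  expect_warning(z <- distance_series(tr, 1, 1), "degenerate")
  expect_equal(z, rep(0, 5))
})

test_that("a toggling contact shows the planted in-cutoff fraction", {
  top <- mk_structure(rbind(c(0, 0, 0), c(4, 0, 0)),
                      chain = c("A", "B"), resid = c(1, 1))
  set.seed(6)
  inside <- runif(2000) < 0.75
  frames <- lapply(inside, function(ok)
    rbind(c(0, 0, 0), c(if (ok) 4.0 else 6.0, 0, 0)))
  tr <- mk_trajectory(top, frames)
  frac <- mean(distance_series(tr, 1, 2) < 4.5)
  expect_equal(frac, mean(inside))
  expect_gt(frac, 0.70); expect_lt(frac, 0.80)
})

test_that("rmsd is invariant under rigid transforms of whole frames", {
  toy <- make_toy_fold(12, "helix")
  tr <- sample_trajectory(elastic_model(toy, 0.4), 20, seed = 51)
  base <- rmsd_series(tr, toy)
  R <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  moved <- tr
  for (k in 1:20)
    moved$frames[, , k] <- sweep(moved$frames[, , k] %*% t(R), 2L,
                                 c(5, -2, 7), `+`)
  expect_equal(rmsd_series(moved, toy), base, tolerance = 1e-8)
})

test_that("rmsf is equivariant under frame reordering", {
  toy <- make_toy_fold(10, "chain")
  tr <- sample_trajectory(elastic_model(toy, 0.4), 30, seed = 61)
  shuffled <- tr
  shuffled$frames <- tr$frames[, , rev(seq_len(30))]
  expect_equal(rmsf(shuffled)$rmsf, rmsf(tr)$rmsf, tolerance = 1e-10)
})

test_that("frame-wise distances obey the triangle inequality", {
  toy <- make_toy_fold(9, "helix")
  tr <- sample_trajectory(elastic_model(toy, 0.6), 50, seed = 71)
  dij <- distance_series(tr, 1, 5)
  dik <- distance_series(tr, 1, 9)
  dkj <- distance_series(tr, 9, 5)
  expect_true(all(abs(dik - dkj) <= dij + 1e-9))
  expect_true(all(dij <= dik + dkj + 1e-9))
})
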