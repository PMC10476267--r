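# Trajectory standardization, k-means clustering, cross-condition matching.

test_that("standardized trajectory columns have median 0 and SD 1", {
  fix <- make_bridged(n = 80, noise = 0.2, seed = 41,
                      fractions = equal_archetype_fractions(0.15))
  traj <- build_trajectories(fix$bridged, rownames(fix$bridged$log2))
  for (j in 1:3) {
    expect_lt(abs(stats::median(traj[, j])), 1e-9)
    expect_lt(abs(bridgeTMT:::pop_sd(traj[, j]) - 1), 1e-9)
  }
  expect_error(build_trajectories(fix$bridged, character(0)), "empty")
  expect_error(build_trajectories(fix$bridged, "NOPE"), "NOPE")
})

test_that("standardization errors on a zero-variance column", {
  fix <- make_bridged(n = 20, noise = 0, seed = 42, base_log2_sd = 0,
                      fractions = numeric(0))
  # flat noiseless proteome: every trajectory column is constant
  expect_error(build_trajectories(fix$bridged, rownames(fix$bridged$log2)),
               "zero standard deviation")
})

test_that("noiseless same-archetype trajectories are identical vectors", {
  fix <- make_bridged(n = 50, noise = 0, seed = 43, base_log2_sd = 0,
                      fractions = equal_archetype_fractions())
  traj <- build_trajectories(fix$bridged, fix$truth$protein_id)
  arch <- planted_archetypes(fix$truth, rownames(traj))
  for (a in unique(arch)) {
    block <- traj[arch == a, , drop = FALSE]
    expect_lt(max(abs(sweep(block, 2, block[1, ]))), 1e-9)
  }
})

test_that("k-means separates well-separated points with zero inertia, deterministically", {
  set.seed(44)
  centers <- matrix(c(0, 0, 0, 5, 5, 5, -5, 5, 0, 5, -5, 0, 0, 0, 9),
                    nrow = 5, byrow = TRUE)
  x <- centers[rep(1:5, each = 3), ]
  rownames(x) <- sprintf("P%02d", 1:15)
  km <- kmeans_cluster(x, k = 5, seed = 7, n_restarts = 20)
  expect_equal(km$inertia, 0)
  expect_equal(length(unique(km$assignments[seq(1, 15, 3)])), 5)
  expect_true(all(km$assignments == km$assignments[rep(seq(1, 15, 3), each = 3)]))
  km2 <- kmeans_cluster(x, k = 5, seed = 7, n_restarts = 20)
  expect_identical(km$assignments, km2$assignments)
  expect_identical(km$inertia, km2$inertia)
})

test_that("1-D toy {0,0,1,1,10,10} at k=3 recovers the exact partition", {
  x <- matrix(c(0, 0, 1, 1, 10, 10), ncol = 1,
              dimnames = list(letters[1:6], NULL))
  km <- kmeans_cluster(x, k = 3, seed = 1, n_restarts = 25)
  expect_equal(km$inertia, 0)
  expect_equal(km$assignments[["a"]], km$assignments[["b"]])
  expect_equal(km$assignments[["c"]], km$assignments[["d"]])
  expect_equal(km$assignments[["e"]], km$assignments[["f"]])
  expect_equal(length(unique(km$assignments)), 3)
})

test_that("too few distinct points is a clustering error", {
  x <- matrix(rep(c(0, 1), each = 6), ncol = 2,
              dimnames = list(paste0("p", 1:6), NULL))
  expect_error(kmeans_cluster(x, k = 5), "distinct")
})

test_that("best-of-restarts inertia is no worse than any single restart", {
  set.seed(45)
  x <- matrix(rnorm(200), ncol = 2,
              dimnames = list(sprintf("P%03d", 1:100), NULL))
  best <- kmeans_cluster(x, k = 4, seed = 9, n_restarts = 30)
  singles <- vapply(1:10, function(s) {
    kmeans_cluster(x, k = 4, seed = s, n_restarts = 1)$inertia
  }, numeric(1))
  expect_true(all(best$inertia <= singles + 1e-9))
})

test_that("cluster matching recovers identity and label permutations", {
  fix <- make_bridged(n = 120, noise = 0.1, seed = 46,
                      fractions = equal_archetype_fractions())
  traj <- build_trajectories(fix$bridged, fix$truth$protein_id)
  km <- kmeans_cluster(traj, k = 5, seed = 3, n_restarts = 20)
  self <- match_clusters(km, km)
  expect_equal(self$mapping, 1:5)
  expect_equal(self$total_distance, 0)
  expect_equal(self$overlap$n_shared, km$sizes)
  expect_true(all(self$overlap$n_a_only == 0 & self$overlap$n_b_only == 0))

  perm <- c(3, 5, 1, 2, 4)
  km_perm <- km
  km_perm$assignments <- stats::setNames(perm[km$assignments],
                                         names(km$assignments))
  km_perm$centers <- km$centers[order(perm), ]
  m <- match_clusters(km, km_perm)
  expect_equal(m$mapping, perm)
  expect_equal(m$total_distance, 0)
})

test_that("matching distance equals the brute-force assignment minimum", {
  set.seed(47)
  for (i in 1:5) {
    a <- list(k = 5, centers = matrix(rnorm(15), 5),
              assignments = stats::setNames(sample(1:5, 40, TRUE),
                                            sprintf("P%02d", 1:40)))
    b <- list(k = 5, centers = matrix(rnorm(15), 5),
              assignments = stats::setNames(sample(1:5, 40, TRUE),
                                            sprintf("P%02d", 1:40)))
    class(a) <- class(b) <- "cluster_model"
    m <- match_clusters(a, b)
    dmat <- outer(1:5, 1:5, Vectorize(function(i, j) {
      sqrt(sum((a$centers[i, ] - b$centers[j, ])^2))
    }))
    expect_equal(m$total_distance, assignment_brute_force(dmat),
                 tolerance = 1e-12)
  }
  b$k <- 4
  expect_error(match_clusters(a, b), "different k")
})

test_that("archetype recovery: ARI 1 noiseless, high under measurement noise", {
  fix0 <- make_bridged(n = 250, noise = 0, seed = 48, base_log2_sd = 0,
                       fractions = equal_archetype_fractions())
  traj0 <- build_trajectories(fix0$bridged, fix0$truth$protein_id)
  km0 <- kmeans_cluster(traj0, k = 5, seed = 17, n_restarts = 30)
  expect_equal(ari(km0$assignments,
                   planted_archetypes(fix0$truth, names(km0$assignments))), 1)

  fix1 <- make_bridged(n = 250, noise = 0.25, seed = 48, base_log2_sd = 0,
                       fractions = equal_archetype_fractions())
  traj1 <- build_trajectories(fix1$bridged, fix1$truth$protein_id)
  km1 <- kmeans_cluster(traj1, k = 5, seed = 17, n_restarts = 30)
  expect_gte(ari(km1$assignments,
                 planted_archetypes(fix1$truth, names(km1$assignments))), 0.8)
})
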