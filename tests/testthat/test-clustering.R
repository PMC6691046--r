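test_that("pre-downsampling is uniform without replacement", {
  p <- make_profile(matrix(1:10, 10, 1), event_ids = 1:10)
  all10 <- pre_downsample(p, 10, seed = 1)
  expect_setequal(all10$exprs[, 1], 1:10)
  one <- pre_downsample(p, 1, seed = 2)
  expect_equal(n_events(one), 1)
  expect_warning(pre_downsample(p, 20, seed = 3), "keeping all")

  # per-event inclusion frequency of n = 5 from 10 over seeded repeats
  hits <- numeric(10)
  for (s in 1:10000) {
    kept <- pre_downsample(p, 5, seed = s)$event_ids
    hits[kept] <- hits[kept] + 1
  }
  expect_true(all(abs(hits / 10000 - 0.5) < 0.02))
})

test_that("local density counts neighbors within the adaptive radius", {
  same <- matrix(1, 5, 2, dimnames = list(NULL, c("x", "y")))
  expect_equal(estimate_local_density(same), rep(5, 5))
  expect_error(estimate_local_density(same[1, , drop = FALSE]), "fewer")

  withr::with_seed(8, {
    blob <- matrix(runif(300 * 2), 300, 2) # tight uniform square
    outlier <- c(100, 100)
    X <- rbind(blob, outlier)
    colnames(X) <- c("x", "y")
    dens <- estimate_local_density(X)
    expect_lt(dens[301], min(dens[1:300]))

    # two-blob fixture against the exhaustive pairwise oracle
    X2 <- rbind(matrix(rnorm(150 * 3), 150, 3),
                matrix(rnorm(50 * 3, mean = 6), 50, 3))
    colnames(X2) <- paste0("m", 1:3)
    dens2 <- estimate_local_density(X2, seed = 4)
    Dsub <- as.matrix(stats::dist(X2))
    diag(Dsub) <- Inf
    r <- 5 * stats::median(apply(Dsub, 1, min))
    expect_equal(dens2, oracle_density_counts(X2, r))
  })
})

test_that("density-dependent downsampling hits its target fraction", {
  spec <- clustering_spec("m1", k = 2, downsample_fraction = 0.05)
  X <- matrix(rnorm(10000), 10000, 1, dimnames = list(NULL, "m1"))
  kept <- density_dependent_downsample(X, rep(7, 10000), spec, seed = 5)
  expect_gt(length(kept), 400) # binomial 99.9% interval around 500
  expect_lt(length(kept), 600)

  spec_all <- clustering_spec("m1", k = 2, downsample_fraction = 1,
                              outlier_density_percentile = 0,
                              target_density_percentile = 100)
  expect_equal(density_dependent_downsample(X, rep(1, 10000), spec_all, 1),
               1:10000)
  expect_error(density_dependent_downsample(X, rep(1, 3), spec, 1),
               "align")
})

test_that("density-dependent downsampling over-retains rare populations", {
  withr::with_seed(12, {
    X <- rbind(matrix(rnorm(9900 * 2, mean = 0, sd = 0.5), 9900, 2),
               matrix(rnorm(100 * 2, mean = 8, sd = 0.5), 100, 2))
    colnames(X) <- c("m1", "m2")
    rare <- c(rep(FALSE, 9900), rep(TRUE, 100))
    dens <- estimate_local_density(X, seed = 3)
    spec <- clustering_spec(c("m1", "m2"), k = 2,
                            downsample_fraction = 0.05)
    kept <- density_dependent_downsample(X, dens, spec, seed = 6)
    rare_prop <- mean(rare[kept])
    expect_gt(rare_prop, 0.01)   # rare blob enriched above its 1% abundance
  })
})

test_that("agglomerative clustering recovers separated blobs", {
  withr::with_seed(19, {
    labels <- rep(1:2, each = 100)
    X <- rbind(matrix(rnorm(100 * 3, 0, 0.3), 100, 3),
               matrix(rnorm(100 * 3, 5, 0.3), 100, 3))
    colnames(X) <- paste0("m", 1:3)
    spec <- clustering_spec(paste0("m", 1:3), k = 2)
    model <- fit_clusters(X, spec)
    tab <- table(model$fit_assignments, labels)
    expect_equal(sum(apply(tab, 1, max)), 200) # partition == blob labels

    # k = n gives singleton clusters whose centroids are the events
    small <- X[1:8, ]
    m8 <- fit_clusters(small, clustering_spec(paste0("m", 1:3), k = 8))
    expect_equal(m8$centroids[order(m8$centroids[, 1]), ],
                 small[order(small[, 1]), ], ignore_attr = TRUE)

    # duplicating every event leaves the centroid set unchanged
    dup <- fit_clusters(rbind(X, X), spec)
    expect_equal(dup$centroids[order(dup$centroids[, 1]), ],
                 model$centroids[order(model$centroids[, 1]), ],
                 tolerance = 1e-8)
    expect_error(fit_clusters(X[1:3, ], clustering_spec(paste0("m", 1:3),
                                                        k = 10)),
                 "fewer events")
  })
})

test_that("upsampling assigns by nearest centroid with low-id ties", {
  model <- structure(
    list(centroids = matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE,
                            dimnames = list(NULL, c("m1", "m2"))),
         k = 2L, markers = c("m1", "m2")),
    class = "cluster_model")
  X <- matrix(c(0, 0, 5, 5, 2.5, 2.5), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("m1", "m2")))
  a <- upsample_assign(model, X)
  expect_equal(a, c(1L, 2L, 1L)) # equidistant midpoint -> lowest id
  expect_equal(upsample_assign(model, make_profile(matrix(numeric(0), 0, 2),
                                                   c("m1", "m2"))),
               integer(0))
  expect_error(upsample_assign(model, make_profile(matrix(0, 1, 1), "m1")),
               "m2")

  withr::with_seed(29, {
    X2 <- rbind(matrix(rnorm(200 * 2, 0, 0.3), 200, 2),
                matrix(rnorm(200 * 2, 6, 0.3), 200, 2))
    colnames(X2) <- c("m1", "m2")
    spec <- clustering_spec(c("m1", "m2"), k = 2)
    fit <- fit_clusters(X2, spec)
    agree <- mean(upsample_assign(fit, X2) == fit$fit_assignments)
    expect_gte(agree, 0.95)
  })
})

test_that("cluster statistics use unweighted means of individual medians", {
  one <- list(I1 = make_profile(matrix(c(1, 2, 3), 3, 1), "m1"))
  st <- compute_cluster_stats(list(I1 = rep(1L, 3)), one, "m1", k = 1)
  expect_equal(unname(st$medians[1, "I1", "m1"]), 2)
  expect_equal(unname(st$mean_of_medians[1, "m1"]), 2)

  two <- list(I1 = make_profile(matrix(rep(1, 10), 10, 1), "m1"),
              I2 = make_profile(matrix(rep(3, 2), 2, 1), "m1"))
  st2 <- compute_cluster_stats(list(I1 = rep(1L, 10), I2 = rep(1L, 2)),
                               two, "m1", k = 1)
  expect_equal(unname(st2$mean_of_medians[1, "m1"]), 2) # unweighted despite 10 vs 2

  withr::with_seed(33, {
    profs <- list(I1 = make_profile(matrix(rnorm(40), 20, 2)),
                  I2 = make_profile(matrix(rnorm(30), 15, 2)))
    asg <- list(I1 = sample(1:4, 20, TRUE), I2 = sample(1:4, 15, TRUE))
    st3 <- compute_cluster_stats(asg, profs, c("m1", "m2"), k = 4)
    expect_equal(sum(st3$counts), 35)
    expect_equal(unname(st3$total), unname(rowSums(st3$counts)))
  })
})
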