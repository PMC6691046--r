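test_that("backbone distance is Euclidean over backbone markers", {
  spec <- backbone_spec(c("b1", "b2"), threshold = 3)
  a <- c(b1 = 1, b2 = 2, other = 99)
  expect_equal(backbone_distance(a, a, spec), 0)
  b <- c(b1 = 1 + 3, b2 = 2 + 4)
  expect_equal(backbone_distance(a, b, spec), 5)
  expect_error(backbone_distance(a, c(b1 = 0), spec), "b2")

  # brute-force oracle on random pairs
  spec8 <- backbone_spec(paste0("m", 1:8))
  withr::with_seed(31, {
    for (i in 1:100) {
      x <- stats::setNames(rnorm(8), paste0("m", 1:8))
      y <- stats::setNames(rnorm(8), paste0("m", 1:8))
      manual <- 0
      for (m in paste0("m", 1:8)) manual <- manual + (x[[m]] - y[[m]])^2
      expect_equal(backbone_distance(x, y, spec8), sqrt(manual),
                   tolerance = 1e-9)
    }
  })
})

test_that("identical profiles match completely at distance zero", {
  X <- matrix(rnorm(30), 10, 3)
  A <- make_profile(X)
  m <- match_profiles(A, A, backbone_spec(paste0("m", 1:3)))
  expect_equal(nrow(m$pairs), 10)
  expect_equal(max(m$pairs$distance), 0)
  expect_equal(sort(m$pairs$index_a), 1:10)
  expect_equal(m$pairs$index_a, m$pairs$index_b)
  expect_length(m$unmatched_a, 0)
})

test_that("a threshold below all inter-profile distances matches nothing", {
  A <- make_profile(matrix(0, 4, 2))
  B <- make_profile(matrix(10, 4, 2))
  m <- match_profiles(A, B, backbone_spec(c("m1", "m2"), threshold = 1))
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_a, 1:4)
  expect_equal(m$unmatched_b, 1:4)
})

test_that("matching equals the exhaustive mutual-NN oracle on jittered copies", {
  withr::with_seed(17, {
    for (rep in 1:25) {
      n <- sample(3:8, 1)
      XA <- matrix(rnorm(n * 3), n, 3)
      XB <- XA[sample(n), ] + matrix(rnorm(n * 3, sd = 0.3), n, 3)
      thr <- sample(c(0.5, 1, 2, 10), 1)
      A <- make_profile(XA)
      B <- make_profile(XB)
      m <- match_profiles(A, B, backbone_spec(paste0("m", 1:3), thr))
      want <- oracle_mutual_nn(XA, XB, thr)
      expect_equal(pairs_matrix(m), oracle_pairs_matrix(want))
    }
  })
})

test_that("matching is symmetric in its two profiles", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      A <- make_profile(matrix(rnorm(6 * 2), 6, 2))
      B <- make_profile(matrix(rnorm(9 * 2), 9, 2))
      spec <- backbone_spec(c("m1", "m2"), threshold = 2)
      ab <- match_profiles(A, B, spec)$pairs
      ba <- match_profiles(B, A, spec)$pairs
      expect_equal(ab[order(ab$index_a), c("index_a", "index_b")],
                   stats::setNames(ba[order(ba$index_b),
                                      c("index_b", "index_a")],
                                   c("index_a", "index_b")),
                   ignore_attr = TRUE)
    }
  })
})

test_that("merging averages the backbone and copies specific markers", {
  spec <- backbone_spec(c("b1", "b2"))
  A <- make_profile(matrix(c(1, 1, 5), 1, 3),
                    markers = c("b1", "b2", "a1"), panel_id = "#A")
  B <- make_profile(matrix(c(3, 1, 7), 1, 3),
                    markers = c("b1", "b2", "c1"), panel_id = "#B")
  m <- match_profiles(A, B, spec)
  out <- merge_two(A, B, m, spec)
  expect_equal(profile_markers(out), c("b1", "b2", "a1", "c1"))
  expect_equal(unname(out$exprs[1, ]), c(2, 1, 5, 7))

  # identical backbone values pass through unchanged
  B2 <- make_profile(matrix(c(1, 1, 7), 1, 3),
                     markers = c("b1", "b2", "c1"))
  out2 <- merge_two(A, B2, match_profiles(A, B2, spec), spec)
  expect_equal(unname(out2$exprs[1, c("b1", "b2")]), c(1, 1))

  # shared non-backbone marker collides
  B3 <- make_profile(matrix(c(1, 1, 9), 1, 3),
                     markers = c("b1", "b2", "a1"))
  expect_error(merge_two(A, B3, match_profiles(A, B3, spec), spec),
               "a1")
})

test_that("a zero-noise two-panel split merges back to the source exactly", {
  spec <- tiny_cohort_spec(n_events = 300)
  gen <- generate_individual(spec, "I1", seed = 77)
  tubes <- split_panels(gen$profile, spec$panels, 0, seed = 78)
  bb <- backbone_spec(c("b1", "b2", "b3"), threshold = 3)
  res <- merge_panelset(tubes, bb)
  expect_equal(res$n_merged, 300)
  expect_equal(res$n_excluded, 0)
  expect_equal(matching_accuracy(res, tubes), 1)
  ids <- tubes$P1$event_ids[res$provenance[, "P1"]]
  orig <- gen$profile$exprs[match(ids, gen$profile$event_ids),
                            profile_markers(res$merged)]
  expect_equal(unname(res$merged$exprs), unname(orig))
})

test_that("three identical profiles merge without exclusions", {
  X <- matrix(rnorm(20 * 2), 20, 2)
  profs <- list(P1 = make_profile(X, c("b1", "b2"), panel_id = "P1"),
                P2 = make_profile(X, c("b1", "b2"), panel_id = "P2"),
                P3 = make_profile(X, c("b1", "b2"), panel_id = "P3"))
  res <- merge_panelset(profs, backbone_spec(c("b1", "b2")))
  expect_equal(res$n_merged, 20)
  expect_equal(res$n_excluded, 0)
  expect_error(merge_panelset(profs, backbone_spec(c("b1", "b2")),
                              order = c("P1", "PX")),
               "unknown panel")
})

test_that("merge accounting is conserved on random instances", {
  withr::with_seed(41, {
    for (rep in 1:8) {
      sizes <- sample(5:20, 3)
      profs <- list(
        P1 = make_profile(matrix(rnorm(sizes[1] * 2), sizes[1], 2),
                          c("b1", "b2"), panel_id = "P1"),
        P2 = make_profile(matrix(rnorm(sizes[2] * 2), sizes[2], 2),
                          c("b1", "b2"), panel_id = "P2"),
        P3 = make_profile(matrix(rnorm(sizes[3] * 2), sizes[3], 2),
                          c("b1", "b2"), panel_id = "P3")
      )
      res <- merge_panelset(profs, backbone_spec(c("b1", "b2"),
                                                 threshold = 1.5))
      expect_lte(res$n_merged, min(sizes))
      expect_equal(res$n_excluded, sum(sizes) - 3 * res$n_merged)
      rep_tab <- merge_report(res)
      comb <- rep_tab[nrow(rep_tab), ]
      expect_equal(comb$n_excluded,
                   merge_accounting(rep_tab$n_cells[1:3], comb$n_cells))
    }
  })
})

test_that("merge reports mirror the accounting identity", {
  # published six-donor accounting reproduces from the printed counts alone
  expect_equal(merge_accounting(c(237039, 192201, 139218), 139104), 151146)
  expect_equal(merge_accounting(c(249773, 249003, 229388), 229058), 40990)

  empty <- list(P1 = make_profile(matrix(numeric(0), 0, 1), "b1"),
                P2 = make_profile(matrix(numeric(0), 0, 1), "b1"))
  res <- merge_panelset(empty, backbone_spec("b1"))
  tab <- merge_report(res)
  expect_equal(tab$n_cells, c(0, 0, 0))
  expect_equal(tab$n_excluded[3], 0)
})
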