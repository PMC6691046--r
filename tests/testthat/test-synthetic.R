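test_that("cohort generation is deterministic given spec and seed", {
  spec <- make_hiv_cohort_preset(seed = 5, n_events = 100)
  a <- generate_individual(spec, "HEA-1", seed = 11)
  b <- generate_individual(spec, "HEA-1", seed = 11)
  expect_identical(a$profile$exprs, b$profile$exprs)
  expect_identical(a$truth, b$truth)
  sa <- split_panels(a$profile, spec$panels, 0.05, seed = 3)
  sb <- split_panels(b$profile, spec$panels, 0.05, seed = 3)
  expect_identical(sa[["#A"]]$exprs, sb[["#A"]]$exprs)
  expect_identical(sa[["#C"]]$event_ids, sb[["#C"]]$event_ids)
})

test_that("population sampling follows the condition weights", {
  universe <- c("m1", "m2")
  panels <- list(panel_definition("P", universe, universe))
  mk <- function(v) stats::setNames(v, universe)
  pops <- list(
    population_spec("p1", mk(c(1, 2)), sd = 0, abundance = c(A = 0.7)),
    population_spec("p2", mk(c(5, 6)), sd = 0, abundance = c(A = 0.3))
  )
  spec <- cohort_spec(pops, universe, panels, c(I1 = "A"),
                      n_events = 10000, backbone_noise_sd = 0, seed = 1)
  gen <- generate_individual(spec, "I1", seed = 2)
  frac <- mean(gen$truth$population == "p1")
  # binomial 99% interval around 0.7 at n = 10,000
  expect_gt(frac, 0.685)
  expect_lt(frac, 0.715)
  # sd -> 0 degenerate draw: events sit exactly on the population mean
  rows1 <- gen$truth$population == "p1"
  expect_true(all(gen$profile$exprs[rows1, "m1"] == 1))
  expect_true(all(gen$profile$exprs[!rows1, "m2"] == 6))

  pops10 <- list(
    population_spec("p1", mk(c(1, 2)), sd = 0.1,
                    abundance = c(A = 1, B = 0)),
    population_spec("p2", mk(c(5, 6)), sd = 0.1,
                    abundance = c(A = 0, B = 1))
  )
  spec10 <- cohort_spec(pops10, universe, panels, c(I1 = "A"),
                        n_events = 500, seed = 1)
  gen10 <- generate_individual(spec10, "I1", seed = 3)
  expect_true(all(gen10$truth$population == "p1"))
})

test_that("all-zero condition weights are a spec error", {
  universe <- c("m1")
  panels <- list(panel_definition("P", universe, universe))
  pops <- list(population_spec("p1", c(m1 = 0), sd = 1,
                               abundance = c(A = 1, B = 0)))
  expect_error(
    cohort_spec(pops, universe, panels, c(I1 = "B"), n_events = 10),
    "all-zero"
  )
})

test_that("panel splitting preserves content and models tube noise", {
  spec <- tiny_cohort_spec(n_events = 150)
  gen <- generate_individual(spec, "I1", seed = 9)
  tubes <- split_panels(gen$profile, spec$panels, backbone_noise_sd = 0,
                        seed = 10)
  # zero noise: each tube's backbone equals the full profile, row-permuted
  for (tube in tubes) {
    ord <- match(gen$profile$event_ids, tube$event_ids)
    expect_equal(tube$exprs[ord, c("b1", "b2", "b3")],
                 gen$profile$exprs[, c("b1", "b2", "b3")])
  }
  # panels sharing all markers give row permutations of each other
  universe <- c("x", "y")
  panels2 <- list(panel_definition("Q1", universe, universe),
                  panel_definition("Q2", universe, universe))
  full <- make_profile(matrix(rnorm(40), 20, 2), markers = universe,
                       event_ids = 1:20)
  tb <- split_panels(full, panels2, 0, seed = 4)
  o1 <- order(tb$Q1$event_ids)
  o2 <- order(tb$Q2$event_ids)
  expect_equal(tb$Q1$exprs[o1, ], tb$Q2$exprs[o2, ])
  # unknown panel marker is a spec error
  bad <- list(panel_definition("R", c("x", "z"), "x"))
  expect_error(split_panels(full, bad, 0, 1), "absent")
})

test_that("backbone noise produces the chi-distributed pair distances", {
  spec <- make_hiv_cohort_preset(seed = 2, n_events = 400,
                                 backbone_noise_sd = 0.05)
  gen <- generate_individual(spec, "HEA-1", seed = 21)
  tubes <- split_panels(gen$profile, spec$panels, backbone_noise_sd = 0.05,
                        seed = 22)
  bb <- spec$panels[[1]]$backbone
  a <- tubes[["#A"]]
  b <- tubes[["#B"]]
  ord <- match(a$event_ids, b$event_ids)
  d <- sqrt(rowSums((a$exprs[, bb] - b$exprs[ord, bb])^2))
  # independent simulation oracle for the mean of ||N(0, 0.05^2 I_14) x 2||
  sim <- withr::with_seed(99, {
    mean(sqrt(rowSums(matrix(rnorm(20000 * 14, sd = 0.05 * sqrt(2)),
                             20000, 14)^2)))
  })
  expect_equal(mean(d), sim, tolerance = 0.05)
  expect_equal(sim, 0.26, tolerance = 0.05)
})

test_that("the preset cohort encodes the study design", {
  spec <- make_hiv_cohort_preset(seed = 1, n_events = 50)
  expect_setequal(spec$panels[[1]]$backbone,
                  c("CD1c", "CD3", "CD11c", "CD14", "CD16", "CD19", "CD32",
                    "CD64", "CD66", "CD86", "CD123", "CD141", "Granzyme B",
                    "HLADR"))
  expect_equal(vapply(spec$panels, function(p) length(p$markers),
                      integer(1)),
               c(35L, 32L, 33L), ignore_attr = TRUE)
  expect_equal(length(spec$marker_universe), 72)
  expect_equal(unname(table(spec$individuals)), c(3L, 3L),
               ignore_attr = TRUE)
  # preset effect sizes: activation markers shifted by >= 1 on monocytes
  mono <- Filter(function(p) p$name == "monocyte", spec$populations)[[1]]
  expect_gte(mono$shift$HIV[["TLR2"]], 1.0)
  expect_gte(mono$shift$HIV[["CD11b"]], 1.0)
  expect_identical(make_hiv_cohort_preset(seed = 7, n_events = 50),
                   make_hiv_cohort_preset(seed = 7, n_events = 50))
})

test_that("zero-noise splits are exactly invertible by backbone matching", {
  for (seed in 1:3) {
    spec <- tiny_cohort_spec(n_events = 60, seed = seed)
    gen <- generate_individual(spec, "I1", seed = seed + 50)
    tubes <- split_panels(gen$profile, spec$panels, 0, seed = seed + 60)
    m <- match_profiles(tubes$P1, tubes$P2,
                        backbone_spec(c("b1", "b2", "b3"), threshold = 0.5))
    expect_equal(nrow(m$pairs), 60)
    expect_equal(tubes$P1$event_ids[m$pairs$index_a],
                 tubes$P2$event_ids[m$pairs$index_b])
  }
})
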