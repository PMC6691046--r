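# Independent oracles, coded naively so they share no machinery with the
# package implementations they check.

# Exhaustive mutual-nearest-neighbor matcher: every round scans all
# remaining pairs, pairs mutual nearest neighbors within the threshold,
# removes them, and repeats until stable. Ties go to the lowest index.
oracle_mutual_nn <- function(XA, XB, threshold) {
  dist_ab <- function(a, b) sqrt(sum((XA[a, ] - XB[b, ])^2))
  rem_a <- seq_len(nrow(XA))
  rem_b <- seq_len(nrow(XB))
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    if (!length(rem_a) || !length(rem_b)) break
    nn_of_a <- vapply(rem_a, function(a) {
      d <- vapply(rem_b, function(b) dist_ab(a, b), numeric(1))
      rem_b[which.min(d)]
    }, integer(1))
    nn_of_b <- vapply(rem_b, function(b) {
      d <- vapply(rem_a, function(a) dist_ab(a, b), numeric(1))
      rem_a[which.min(d)]
    }, integer(1))
    new_a <- integer(0); new_b <- integer(0)
    for (i in seq_along(rem_a)) {
      a <- rem_a[i]
      b <- nn_of_a[i]
      if (nn_of_b[match(b, rem_b)] == a && dist_ab(a, b) <= threshold) {
        new_a <- c(new_a, a)
        new_b <- c(new_b, b)
      }
    }
    if (!length(new_a)) break
    pairs <- rbind(pairs, cbind(new_a, new_b))
    rem_a <- setdiff(rem_a, new_a)
    rem_b <- setdiff(rem_b, new_b)
  }
  pairs[order(pairs[, 1]), , drop = FALSE]
}

# Canonical numeric pair matrices for comparing matchings (handles the
# zero-pair case uniformly).
pairs_matrix <- function(m) {
  o <- order(m$pairs$index_a)
  matrix(as.numeric(cbind(m$pairs$index_a, m$pairs$index_b)[o, ]),
         ncol = 2)
}
oracle_pairs_matrix <- function(want) matrix(as.numeric(want), ncol = 2)

# Brute-force density: count of events within radius r, self included.
oracle_density_counts <- function(X, r) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((X - matrix(X[i, ], n, ncol(X), byrow = TRUE))^2))
    sum(d <= r)
  }, numeric(1))
}

# Naive complete-linkage agglomeration: returns merge heights in order.
oracle_complete_linkage_heights <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Small helper: profile from a matrix with auto marker names.
make_profile <- function(X, markers = paste0("m", seq_len(ncol(X))),
                         transformed = TRUE, ...) {
  colnames(X) <- markers
  cyto_profile(X, transformed = transformed, ...)
}

# A minimal two-panel cohort for merge/recovery tests.
tiny_cohort_spec <- function(n_events = 200, backbone_noise_sd = 0,
                             seed = 1) {
  universe <- c("b1", "b2", "b3", "a1", "a2", "c1", "c2")
  backbone <- c("b1", "b2", "b3")
  panels <- list(
    panel_definition("P1", c(backbone, "a1", "a2"), backbone),
    panel_definition("P2", c(backbone, "c1", "c2"), backbone)
  )
  mean1 <- stats::setNames(c(0, 0, 0, 1, 2, 3, 4), universe)
  mean2 <- stats::setNames(c(4, 4, 4, 2, 1, 0, 1), universe)
  pops <- list(
    population_spec("pop1", mean1, sd = 0.3,
                    abundance = c(HEA = 0.5, HIV = 0.5)),
    population_spec("pop2", mean2, sd = 0.3,
                    abundance = c(HEA = 0.5, HIV = 0.5))
  )
  cohort_spec(pops, universe, panels,
              individuals = c(I1 = "HEA"), n_events = n_events,
              backbone_noise_sd = backbone_noise_sd, seed = seed)
}
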