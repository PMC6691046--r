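#' Classify clusters by enrichment trend
#'
#' A cluster is an enrichment-trend cluster (ETC) when its cell abundance
#' is strongly specific to one condition: the fold-change between the two
#' conditions' normalized abundances exceeds `fc_threshold` (default 4).
#' Abundances are per-individual proportions summed within condition, which
#' guards against unequal acquisition depths; a pseudocount (one cell at
#' the smallest individual total, by default) keeps fold-changes finite
#' when a condition has no cells in a cluster. Clusters with fewer than
#' `min_cells` cells over the whole dataset are unassigned.
#'
#' Swapping the condition labels swaps `enriched_HIV` and `enriched_HEA`
#' and inverts the fold-change exactly.
#'
#' @param counts cluster-by-individual count matrix.
#' @param conditions named character vector mapping individual to
#'   condition (`"HEA"` / `"HIV"`).
#' @param fc_threshold fold-change threshold (default 4).
#' @param pseudocount pseudocount in cells, scaled to proportions by the
#'   smallest individual total (default 1).
#' @param min_cells whole-dataset count below which a cluster is
#'   unassigned (default 50).
#' @return data.frame with columns `cluster`, `fold_change`
#'   (HIV over HEA), `label` in
#'   `enriched_HIV` / `enriched_HEA` / `none` / `unassigned`.
#' @export
classify_etc <- function(counts, conditions, fc_threshold = 4,
                         pseudocount = 1, min_cells = 50) {
  counts <- as.matrix(counts)
  ids <- colnames(counts)
  conditions <- conditions[ids]
  if (length(unique(conditions)) < 2L) {
    stop("both conditions need >= 1 individual", call. = FALSE)
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("individual(s) with zero total cells: ",
         paste(ids[totals == 0], collapse = ", "), call. = FALSE)
  }
  props <- sweep(counts, 2, totals, "/")
  a_hiv <- rowSums(props[, conditions == "HIV", drop = FALSE])
  a_hea <- rowSums(props[, conditions == "HEA", drop = FALSE])
  eps <- pseudocount / min(totals)
  fc <- (a_hiv + eps) / (a_hea + eps)
  label <- rep("none", nrow(counts))
  label[fc > fc_threshold] <- "enriched_HIV"
  label[1 / fc > fc_threshold] <- "enriched_HEA"
  label[rowSums(counts) < min_cells] <- "unassigned"
  data.frame(cluster = seq_len(nrow(counts)), fold_change = fc,
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Non-parametric two-sample permutation test
#'
#' Tests the difference between two groups with the two-sided statistic
#' `|mean(x) - mean(y)|` (or a user statistic). If the number of
#' relabelings `choose(n1+n2, n1)` is at most `max_permutations` the null
#' distribution is enumerated exhaustively and
#' `p = #(statistic >= observed) / total`; otherwise Monte-Carlo sampling
#' is used with the add-one convention `p = (1 + exceedances) / (1 + draws)`,
#' so Monte-Carlo p-values are bounded below by `1/(1 + draws)`.
#'
#' @param x,y numeric vectors (nonempty) for the two groups.
#' @param statistic `"meandiff"` (vectorized fast path) or a
#'   `function(x, y)` returning a scalar statistic; larger = more extreme.
#' @param max_permutations exhaustive-enumeration cap and Monte-Carlo draw
#'   count (default 10000; 3v3 and 6v6 designs are always exhaustive).
#' @param seed RNG seed for Monte-Carlo sampling.
#' @return an object of class `perm_test`: list with `observed`,
#'   `p_value`, `n_permutations`, `exhaustive`.
#' @export
#' @examples
#' # complete separation of 3 vs 3: only the observed split and its mirror
#' # reach the maximum statistic among the C(6,3) = 20 relabelings
#' permutation_test(c(10, 11, 12), c(0, 1, 2))$p_value # 0.1
permutation_test <- function(x, y, statistic = "meandiff",
                             max_permutations = 10000, seed = 1) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty",
                                     call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  stat_fun <- if (is.function(statistic)) {
    statistic
  } else {
    function(x, y) abs(mean(x) - mean(y))
  }
  observed <- stat_fun(x, y)
  tol <- max(1e-12, 1e-12 * abs(observed))
  n_total <- choose(n1 + n2, n1)
  if (n_total <= max_permutations) {
    idx <- utils::combn(n1 + n2, n1)
    if (!is.function(statistic)) {
      total <- sum(z)
      s1 <- colSums(matrix(z[idx], nrow = n1))
      stats_all <- abs(s1 / n1 - (total - s1) / n2)
    } else {
      stats_all <- apply(idx, 2, function(i) stat_fun(z[i], z[-i]))
    }
    p <- mean(stats_all >= observed - tol)
    structure(list(observed = observed, p_value = p,
                   n_permutations = n_total, exhaustive = TRUE),
              class = "perm_test")
  } else {
    exceed <- withr::with_seed(seed, {
      count <- 0L
      for (b in seq_len(max_permutations)) {
        i <- sample.int(n1 + n2, n1)
        if (stat_fun(z[i], z[-i]) >= observed - tol) count <- count + 1L
      }
      count
    })
    p <- (1 + exceed) / (1 + max_permutations)
    structure(list(observed = observed, p_value = p,
                   n_permutations = max_permutations, exhaustive = FALSE),
              class = "perm_test")
  }
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4g, p = %.4g (%s, %d relabelings)\n",
              x$observed, x$p_value,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_permutations))
  invisible(x)
}

#' Compare a population's marker intensities between groups
#'
#' For one annotated population (e.g. monocytes), each individual
#' contributes one MSI per marker — the mean expression over that
#' individual's population cells — and the two conditions are compared
#' marker by marker with [permutation_test()]. Individuals with no cells in
#' the population are excluded with a warning.
#'
#' @param profiles named list (by individual) of profiles/matrices.
#' @param masks named list (by individual) of logical vectors selecting
#'   the population's cells.
#' @param markers markers to test.
#' @param conditions named character vector: individual -> condition.
#' @param ... passed to [permutation_test()].
#' @return data.frame with one row per marker: `marker`, `observed`,
#'   `direction` (sign of HIV minus HEA mean MSI), `p_value`,
#'   `n_permutations`, `exhaustive`.
#' @export
compare_population_msi <- function(profiles, masks, markers, conditions,
                                   ...) {
  ids <- names(profiles)
  msi <- matrix(NA_real_, length(ids), length(markers),
                dimnames = list(ids, markers))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    X <- as_cluster_matrix(profiles[[ids[i]]], markers)
    m <- masks[[ids[i]]]
    if (!any(m)) {
      warning("individual ", ids[i],
              " has no cells in the population; excluded", call. = FALSE)
      next
    }
    msi[i, ] <- colMeans(X[m, , drop = FALSE])
    keep[i] <- TRUE
  }
  msi <- msi[keep, , drop = FALSE]
  cond <- conditions[rownames(msi)]
  if (!any(cond == "HIV") || !any(cond == "HEA")) {
    stop("a condition has no individuals with cells in the population",
         call. = FALSE)
  }
  out <- lapply(markers, function(mk) {
    x <- msi[cond == "HIV", mk]
    y <- msi[cond == "HEA", mk]
    pt <- permutation_test(x, y, ...)
    data.frame(marker = mk, observed = pt$observed,
               direction = sign(mean(x) - mean(y)), p_value = pt$p_value,
               n_permutations = pt$n_permutations,
               exhaustive = pt$exhaustive, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
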