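#' Clustering-stage parameters
#'
#' Parameters for the density-normalized downsampling + clustering +
#' upsampling stage. Defaults mirror a standard high-resolution run: 5%
#' density-dependent downsampling, a random pre-downsample of 67,000 cells
#' per sample, and 500 clusters; validation-style runs typically use
#' `k = 100`.
#'
#' @param clustering_markers markers used for density estimation,
#'   clustering and assignment.
#' @param k number of clusters.
#' @param downsample_fraction target kept fraction of the density-dependent
#'   downsampling, in (0, 1].
#' @param pre_downsample_n per-sample uniform pre-downsample size, or `NULL`
#'   to skip.
#' @param outlier_density_percentile events below this density percentile
#'   are discarded as outliers (default 1).
#' @param target_density_percentile percentile of the remaining densities
#'   defining the target density (default 5).
#' @param seed RNG seed for the stochastic steps.
#' @return an object of class `clustering_spec`.
#' @export
clustering_spec <- function(clustering_markers, k = 500,
                            downsample_fraction = 0.05,
                            pre_downsample_n = 67000,
                            outlier_density_percentile = 1,
                            target_density_percentile = 5,
                            seed = 1) {
  if (!length(clustering_markers)) {
    stop("clustering_markers must be nonempty", call. = FALSE)
  }
  check_positive_scalar(k, "k")
  if (downsample_fraction <= 0 || downsample_fraction > 1) {
    stop("downsample_fraction must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(clustering_markers = as.character(clustering_markers), k = as.integer(k),
         downsample_fraction = downsample_fraction,
         pre_downsample_n = pre_downsample_n,
         outlier_density_percentile = outlier_density_percentile,
         target_density_percentile = target_density_percentile,
         seed = seed),
    class = "clustering_spec"
  )
}

#' Uniform random pre-downsample
#'
#' Selects `n` events uniformly at random without replacement (seeded). If
#' the profile holds fewer than `n` events, all are kept with a warning.
#'
#' @param profile a [cyto_profile()].
#' @param n target event count.
#' @param seed RNG seed.
#' @return the downsampled profile.
#' @export
pre_downsample <- function(profile, n, seed = 1) {
  total <- n_events(profile)
  if (n >= total) {
    if (n > total) {
      warning("requested ", n, " events but profile has ", total,
              "; keeping all", call. = FALSE)
      n <- total
    }
  }
  keep <- withr::with_seed(seed, sample.int(total, n))
  profile$exprs <- profile$exprs[keep, , drop = FALSE]
  if (!is.null(profile$event_ids)) profile$event_ids <- profile$event_ids[keep]
  profile
}

as_cluster_matrix <- function(x, markers = NULL) {
  X <- if (inherits(x, "cyto_profile")) x$exprs else as.matrix(x)
  if (!is.null(markers)) {
    missing <- setdiff(markers, colnames(X))
    if (length(missing)) {
      stop("missing marker(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, markers, drop = FALSE]
  }
  X
}

#' Estimate per-event local density
#'
#' Density of event *i* is the number of events (self included) within
#' radius `r` of it, where `r` is `radius_factor` times the median
#' nearest-neighbor distance of a seeded subsample of at most
#' `subsample_n` events. This is the usual kernel for density-dependent
#' downsampling of cytometry data.
#'
#' @param x matrix or [cyto_profile()].
#' @param markers markers to use (default: all columns).
#' @param subsample_n subsample size for the radius estimate (default
#'   2000).
#' @param radius_factor multiple of the median nearest-neighbor distance
#'   (default 5).
#' @param seed RNG seed for the subsample.
#' @return numeric vector of per-event densities.
#' @export
estimate_local_density <- function(x, markers = NULL, subsample_n = 2000,
                                   radius_factor = 5, seed = 1) {
  X <- as_cluster_matrix(x, markers)
  n <- nrow(X)
  if (n < 2L) stop("density undefined for fewer than 2 events",
                   call. = FALSE)
  sub <- if (n > subsample_n) {
    withr::with_seed(seed, sample.int(n, subsample_n))
  } else {
    seq_len(n)
  }
  Dsub <- cross_dist(X[sub, , drop = FALSE], X[sub, , drop = FALSE])
  diag(Dsub) <- Inf
  r <- radius_factor * stats::median(apply(Dsub, 1, min))
  dens <- numeric(n)
  block <- 2000L
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    Db <- cross_dist(X[idx, , drop = FALSE], X)
    dens[idx] <- rowSums(Db <= r)
  }
  dens
}

#' Density-dependent downsampling
#'
#' Equalizes density across phenotypic space so that rare populations
#' survive downsampling: events below the outlier density percentile are
#' removed; events below the target density TD (a low percentile of the
#' remaining densities) are always kept; denser events are kept with
#' probability `TD / density`. If the expected kept fraction still exceeds
#' `downsample_fraction`, a final uniform thinning brings the expected kept
#' count down to `fraction * n`.
#'
#' @param x matrix or [cyto_profile()] (used only for its event count).
#' @param densities per-event densities from [estimate_local_density()].
#' @param spec a [clustering_spec()].
#' @param seed RNG seed.
#' @return integer vector of kept row indices.
#' @export
density_dependent_downsample <- function(x, densities, spec, seed = 1) {
  X <- as_cluster_matrix(x)
  n <- nrow(X)
  if (length(densities) != n) {
    stop("densities must align with the event rows", call. = FALSE)
  }
  od <- stats::quantile(densities, spec$outlier_density_percentile / 100,
                        names = FALSE)
  candidates <- which(densities >= od)
  td <- stats::quantile(densities[candidates],
                        spec$target_density_percentile / 100, names = FALSE)
  keep_prob <- pmin(1, td / densities[candidates])
  expected <- sum(keep_prob)
  target <- spec$downsample_fraction * n
  if (expected > target) keep_prob <- keep_prob * target / expected
  kept <- withr::with_seed(seed, {
    candidates[stats::runif(length(candidates)) < keep_prob]
  })
  sort(kept)
}

#' Fit a k-cluster partition on downsampled cells
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward merge
#' criterion) on the clustering markers, cut at `k` clusters. Cluster
#' centroids are per-cluster medians, the robust location used throughout
#' the downstream statistics.
#'
#' @param x pooled downsampled matrix or [cyto_profile()].
#' @param spec a [clustering_spec()].
#' @return an object of class `cluster_model`: list with `centroids`
#'   (k x markers median matrix), `k`, `markers`, and `fit_assignments`
#'   (cluster id per fitted cell).
#' @export
fit_clusters <- function(x, spec) {
  X <- as_cluster_matrix(x, spec$clustering_markers)
  if (nrow(X) < spec$k) {
    stop("fewer events (", nrow(X), ") than clusters (", spec$k, ")",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  assign <- stats::cutree(hc, k = spec$k)
  centroids <- matrix(NA_real_, spec$k, ncol(X),
                      dimnames = list(NULL, colnames(X)))
  for (cl in seq_len(spec$k)) {
    centroids[cl, ] <- apply(X[assign == cl, , drop = FALSE], 2,
                             stats::median)
  }
  structure(list(centroids = centroids, k = spec$k,
                 markers = spec$clustering_markers,
                 fit_assignments = assign),
            class = "cluster_model")
}

#' Assign every cell to its nearest cluster (full upsampling)
#'
#' After cluster identification on the downsampled subset, every cell of
#' every individual is assigned to the cluster with the nearest centroid
#' (Euclidean distance on the clustering markers); ties go to the lowest
#' cluster id.
#'
#' @param model a `cluster_model` from [fit_clusters()].
#' @param profiles a single profile/matrix or a (named) list of them.
#' @return integer vector of cluster ids, or a named list of such vectors
#'   when `profiles` is a list.
#' @export
upsample_assign <- function(model, profiles) {
  assign_one <- function(x) {
    X <- as_cluster_matrix(x, model$markers)
    if (nrow(X) == 0L) return(integer(0))
    D <- cross_dist(X, model$centroids)
    max.col(-D, ties.method = "first")
  }
  if (inherits(profiles, "cyto_profile") || is.matrix(profiles)) {
    assign_one(profiles)
  } else {
    lapply(profiles, assign_one)
  }
}

#' Per-cluster, per-individual statistics
#'
#' Counts and per-marker medians per (cluster, individual), plus the
#' cluster-level expression value used for categorization: the unweighted
#' mean of the medians of the individuals that have at least one cell in
#' the cluster. The mean signal intensity (MSI) convention for a cell set
#' is its mean expression.
#'
#' @param assignments named list (by individual) of cluster-id vectors from
#'   [upsample_assign()].
#' @param profiles named list (by individual) of profiles/matrices, aligned
#'   with `assignments`.
#' @param markers markers to summarize.
#' @param k number of clusters (default: maximum assigned id).
#' @return an object of class `cluster_stats`: list with `counts`
#'   (k x individuals), `medians` (k x individuals x markers array),
#'   `mean_of_medians` (k x markers), `total` (per-cluster cell count).
#' @export
compute_cluster_stats <- function(assignments, profiles, markers,
                                  k = max(unlist(assignments), 0L)) {
  ids <- names(assignments)
  if (is.null(ids)) {
    ids <- paste0("ind", seq_along(assignments))
    names(assignments) <- ids
    names(profiles) <- ids
  }
  counts <- matrix(0, k, length(ids), dimnames = list(NULL, ids))
  medians <- array(NA_real_, dim = c(k, length(ids), length(markers)),
                   dimnames = list(NULL, ids, markers))
  for (ind in ids) {
    a <- assignments[[ind]]
    X <- as_cluster_matrix(profiles[[ind]], markers)
    if (length(a) != nrow(X)) {
      stop("assignments for ", ind, " do not cover its events",
           call. = FALSE)
    }
    counts[, ind] <- tabulate(a, nbins = k)
    for (cl in unique(a)) {
      medians[cl, ind, ] <- apply(X[a == cl, , drop = FALSE], 2,
                                  stats::median)
    }
  }
  mom <- matrix(NA_real_, k, length(markers),
                dimnames = list(NULL, markers))
  for (cl in seq_len(k)) {
    with_cells <- which(counts[cl, ] > 0)
    if (length(with_cells)) {
      med <- medians[cl, with_cells, , drop = FALSE]
      mom[cl, ] <- apply(matrix(med, nrow = length(with_cells),
                                ncol = length(markers)), 2, mean)
    }
  }
  structure(list(counts = counts, medians = medians,
                 mean_of_medians = mom, total = rowSums(counts)),
            class = "cluster_stats")
}
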