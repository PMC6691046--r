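#' Marker expression ranges
#'
#' Per-marker empirical 5th and 95th percentiles (linear-interpolation
#' convention) over the pooled cells of all individuals. The range anchors
#' the five-category quantization, so extreme tails do not stretch the
#' scale.
#'
#' @param x matrix, [cyto_profile()], or list of them (pooled).
#' @param markers markers to range (default: all columns).
#' @param probs the two percentile probabilities (default `c(0.05, 0.95)`).
#' @return data.frame with columns `marker`, `low`, `high`.
#' @export
compute_marker_ranges <- function(x, markers = NULL,
                                  probs = c(0.05, 0.95)) {
  if (is.list(x) && !inherits(x, "cyto_profile")) {
    mats <- lapply(x, as_cluster_matrix, markers = markers)
    X <- do.call(rbind, mats)
  } else {
    X <- as_cluster_matrix(x, markers)
  }
  if (nrow(X) < 1L) stop("need >= 1 cell to compute ranges", call. = FALSE)
  q <- apply(X, 2, stats::quantile, probs = probs, names = FALSE)
  data.frame(marker = colnames(X), low = q[1, ], high = q[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Quantize expression values into uniform categories
#'
#' The range `[low, high]` is divided into `n_categories` bins of equal
#' width. Values at or below `low` fall in category 1; values at or above
#' `high` fall in the top category; interior bin edges belong to the upper
#' bin. A degenerate range (`low == high`) maps values at or below the
#' constant to 1 and everything above to the top category. Quantization is
#' monotone in the value.
#'
#' @param values numeric vector.
#' @param low,high range bounds (e.g. from [compute_marker_ranges()]).
#' @param n_categories number of categories (default 5, labelled
#'   negative / low / medium / high / bright).
#' @return integer vector of categories in `1..n_categories`.
#' @export
categorize <- function(values, low, high, n_categories = 5) {
  if (high < low) stop("invalid range: high < low", call. = FALSE)
  if (high == low) {
    return(ifelse(values <= low, 1L, as.integer(n_categories)))
  }
  width <- (high - low) / n_categories
  cat <- 1L + floor((values - low) / width)
  as.integer(pmin(pmax(cat, 1L), n_categories))
}

#' Category labels
#'
#' @param n_categories number of categories.
#' @return character vector of labels; for the default 5 categories:
#'   negative, low, medium, high, bright.
#' @export
category_labels <- function(n_categories = 5) {
  if (n_categories == 5) {
    c("negative", "low", "medium", "high", "bright")
  } else {
    paste0("cat", seq_len(n_categories))
  }
}

#' Build the categorical cluster-by-marker heatmap
#'
#' Each entry is the quantized mean-of-individual-medians of a marker in a
#' cluster. Clusters with fewer than `min_cells` cells over the whole
#' dataset cannot support a meaningful median and are set to unassigned
#' (`NA`) across all markers.
#'
#' @param stats a `cluster_stats` from [compute_cluster_stats()].
#' @param ranges data.frame from [compute_marker_ranges()] covering the
#'   same markers.
#' @param min_cells whole-dataset count below which a cluster is
#'   unassigned (default 50).
#' @param n_categories number of categories (default 5).
#' @return an object of class `categorical_heatmap`: list with
#'   `categories` (integer matrix, `NA` rows for unassigned clusters),
#'   `unassigned` (logical vector), `total` (cluster cell counts),
#'   `labels` (category labels).
#' @export
build_heatmap <- function(stats, ranges, min_cells = 50, n_categories = 5) {
  markers <- colnames(stats$mean_of_medians)
  missing <- setdiff(markers, ranges$marker)
  if (length(missing)) {
    stop("ranges missing marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- nrow(stats$mean_of_medians)
  cats <- matrix(NA_integer_, k, length(markers),
                 dimnames = list(NULL, markers))
  for (m in markers) {
    r <- ranges[ranges$marker == m, ]
    cats[, m] <- categorize(stats$mean_of_medians[, m], r$low, r$high,
                            n_categories)
  }
  unassigned <- stats$total < min_cells
  cats[unassigned, ] <- NA_integer_
  structure(list(categories = cats, unassigned = unassigned,
                 total = stats$total,
                 labels = category_labels(n_categories)),
            class = "categorical_heatmap")
}

#' Dendrogram orders for the categorical heatmap
#'
#' Three hierarchical clusterings (Euclidean distance, complete linkage) on
#' the categorical matrix: one over assigned cluster rows (unassigned rows
#' are excluded and appended last), one over the backbone marker columns,
#' and one over the panel-specific marker columns. With fewer than two
#' assigned rows the identity order is returned.
#'
#' @param heatmap a `categorical_heatmap` from [build_heatmap()].
#' @param backbone character vector of backbone marker names.
#' @return list with `row_order`, `backbone_order`, `specific_order`
#'   (integer permutations; marker orders index into the heatmap columns).
#' @export
order_heatmap <- function(heatmap, backbone) {
  cats <- heatmap$categories
  assigned <- which(!heatmap$unassigned)
  row_order <- if (length(assigned) < 2L) {
    seq_len(nrow(cats))
  } else {
    hc <- stats::hclust(stats::dist(cats[assigned, , drop = FALSE]),
                        method = "complete")
    c(assigned[hc$order], which(heatmap$unassigned))
  }
  order_cols <- function(cols) {
    idx <- which(colnames(cats) %in% cols)
    if (length(idx) < 2L) return(idx)
    sub <- cats[assigned, idx, drop = FALSE]
    hc <- stats::hclust(stats::dist(t(sub)), method = "complete")
    idx[hc$order]
  }
  list(row_order = row_order,
       backbone_order = order_cols(backbone),
       specific_order = order_cols(setdiff(colnames(cats), backbone)))
}

#' Define a population annotation rule
#'
#' A rule is a conjunction of category predicates evaluated on a heatmap
#' row: each predicate compares a marker's category against a threshold
#' with `>=` or `<=`.
#'
#' @param population population name to assign.
#' @param ... predicates written as `marker = ">=4"` / `marker = "<=1"`.
#' @return an object of class `annotation_rule`.
#' @export
#' @examples
#' annotation_rule("T cell", "CD3" = ">=4", "CD19" = "<=1", "CD66" = "<=1")
annotation_rule <- function(population, ...) {
  preds <- list(...)
  if (!length(preds)) stop("rule needs >= 1 predicate", call. = FALSE)
  parsed <- lapply(preds, function(p) {
    op <- substr(p, 1, 2)
    if (!op %in% c(">=", "<=")) {
      stop("predicate must start with '>=' or '<=': ", p, call. = FALSE)
    }
    list(op = op, category = as.integer(substring(p, 3)))
  })
  structure(list(population = population,
                 predicates = stats::setNames(parsed, names(preds))),
            class = "annotation_rule")
}

#' Default population annotation rules
#'
#' Declared heuristics mapping lineage-marker category patterns to the
#' major leukocyte populations, evaluated in priority order: granulocytes
#' first (CD66), then lymphocyte lineages (CD3, CD19), monocytes (CD14),
#' NK cells (Granzyme B in the absence of lineage markers), and the
#' dendritic populations (CD11c / CD123 with HLADR). Intended as an
#' editable starting point, not a claim of annotation fidelity.
#'
#' @return list of [annotation_rule()] objects.
#' @export
default_annotation_rules <- function() {
  list(
    annotation_rule("PMN", "CD66" = ">=4"),
    annotation_rule("T cell", "CD3" = ">=4", "CD19" = "<=1", "CD66" = "<=1"),
    annotation_rule("B cell", "CD19" = ">=4", "CD3" = "<=2"),
    annotation_rule("monocyte", "CD14" = ">=4", "CD3" = "<=2",
                    "CD19" = "<=2"),
    annotation_rule("pDC", "CD123" = ">=5", "HLADR" = ">=4", "CD14" = "<=3",
                    "CD3" = "<=2"),
    annotation_rule("NK cell", "Granzyme B" = ">=4", "CD3" = "<=2",
                    "CD19" = "<=2", "CD14" = "<=3", "CD66" = "<=2"),
    annotation_rule("mDC", "CD11c" = ">=4", "HLADR" = ">=4", "CD14" = "<=3",
                    "CD3" = "<=2", "CD19" = "<=2", "CD66" = "<=2"),
    annotation_rule("basophil", "CD123" = ">=5", "HLADR" = "<=2")
  )
}

#' Annotate clusters with population labels
#'
#' The first rule whose predicates all hold on a cluster's category row
#' labels the cluster; clusters matching no rule are `"unannotated"`;
#' unassigned clusters stay `"unassigned"` regardless of rules.
#'
#' @param heatmap a `categorical_heatmap`.
#' @param rules list of [annotation_rule()] objects (default
#'   [default_annotation_rules()]).
#' @return character vector of population labels, one per cluster.
#' @export
annotate_populations <- function(heatmap, rules = default_annotation_rules()) {
  cats <- heatmap$categories
  for (rule in rules) {
    missing <- setdiff(names(rule$predicates), colnames(cats))
    if (length(missing)) {
      stop("rule '", rule$population, "' references missing marker(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  labels <- rep("unannotated", nrow(cats))
  for (i in seq_len(nrow(cats))) {
    if (heatmap$unassigned[i]) {
      labels[i] <- "unassigned"
      next
    }
    for (rule in rules) {
      hold <- vapply(names(rule$predicates), function(m) {
        p <- rule$predicates[[m]]
        v <- cats[i, m]
        if (p$op == ">=") v >= p$category else v <= p$category
      }, logical(1))
      if (all(hold)) {
        labels[i] <- rule$population
        break
      }
    }
  }
  labels
}
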