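#' Backbone specification for cross-panel matching
#'
#' @param markers ordered character vector of backbone marker names (the
#'   markers measured in every panel).
#' @param threshold maximum backbone distance at which two cells are
#'   *acceptable* match candidates (default 3, in arcsinh units).
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(markers, threshold = 3) {
  if (!length(markers)) stop("backbone must contain >= 1 marker",
                             call. = FALSE)
  check_positive_scalar(threshold, "threshold")
  structure(list(markers = as.character(markers), threshold = threshold),
            class = "backbone_spec")
}

#' Backbone distance between two cells
#'
#' Euclidean distance over the backbone marker values of two event rows.
#'
#' @param a,b named numeric vectors (event rows) containing all backbone
#'   markers.
#' @param spec a [backbone_spec()].
#' @return non-negative distance.
#' @export
backbone_distance <- function(a, b, spec) {
  missing <- setdiff(spec$markers, union(names(a), character(0)))
  missing <- union(missing, setdiff(spec$markers, names(b)))
  if (length(missing)) {
    stop("missing backbone marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sqrt(sum((a[spec$markers] - b[spec$markers])^2))
}

#' Match cells across two profiles on their backbone
#'
#' Implements acceptable / non-ambiguous nearest-neighbor matching. In each
#' round, a pair `(a, b)` of still-unmatched cells is matched when `b` is
#' `a`'s nearest unmatched neighbor in B, `a` is `b`'s nearest unmatched
#' neighbor in A (mutuality = non-ambiguity), and their backbone distance is
#' at most the threshold (acceptability). Matched cells are removed and the
#' search repeats on the remainder until a round adds no pair, so cells
#' whose nearest neighbor was claimed by a better partner get a second
#' chance against the residual set.
#'
#' Equidistant nearest neighbors are broken toward the lowest row index,
#' making the procedure deterministic; the resulting pair set is symmetric
#' in A and B.
#'
#' @param A,B transformed [cyto_profile()] objects containing all backbone
#'   markers.
#' @param spec a [backbone_spec()].
#' @return an object of class `merge_match`: list with `pairs` (data.frame
#'   `index_a`, `index_b`, `distance`), `unmatched_a`, `unmatched_b`.
#' @export
match_profiles <- function(A, B, spec) {
  if (!inherits(spec, "backbone_spec")) spec <- backbone_spec(spec)
  XA <- subset_markers(A, spec$markers)$exprs
  XB <- subset_markers(B, spec$markers)$exprs
  na <- nrow(XA); nb <- nrow(XB)
  pa <- integer(0); pb <- integer(0); pd <- numeric(0)
  if (na > 0 && nb > 0) {
    D <- cross_dist(XA, XB)
    rem_a <- seq_len(na); rem_b <- seq_len(nb)
    repeat {
      if (!length(rem_a) || !length(rem_b)) break
      sub <- D[rem_a, rem_b, drop = FALSE]
      nn_b <- max.col(-sub, ties.method = "first")   # per remaining a
      nn_a <- max.col(-t(sub), ties.method = "first") # per remaining b
      mutual <- which(nn_a[nn_b] == seq_along(rem_a))
      dists <- sub[cbind(mutual, nn_b[mutual])]
      ok <- mutual[dists <= spec$threshold]
      if (!length(ok)) break
      pa <- c(pa, rem_a[ok])
      pb <- c(pb, rem_b[nn_b[ok]])
      pd <- c(pd, sub[cbind(ok, nn_b[ok])])
      rem_a <- rem_a[-ok]
      rem_b <- rem_b[-nn_b[ok]]
    }
  } else {
    rem_a <- seq_len(na); rem_b <- seq_len(nb)
  }
  structure(
    list(pairs = data.frame(index_a = pa, index_b = pb, distance = pd),
         unmatched_a = sort(rem_a), unmatched_b = sort(rem_b)),
    class = "merge_match"
  )
}

#' Merge two profiles given a match
#'
#' Each matched pair becomes one output cell: backbone columns take the
#' arithmetic mean of the two contributors; panel-specific columns are
#' copied from their contributor. Output marker order is backbone, then
#' A-specific, then B-specific. A marker shared outside the backbone would
#' collide and is an error.
#'
#' @param A,B the matched [cyto_profile()] objects.
#' @param match a `merge_match` from [match_profiles()].
#' @param spec the [backbone_spec()] used for matching.
#' @return a merged [cyto_profile()] with an attribute `provenance`, a
#'   two-column matrix of contributing row indices (in A and in B).
#' @export
merge_two <- function(A, B, match, spec) {
  bb <- spec$markers
  a_spec <- setdiff(profile_markers(A), bb)
  b_spec <- setdiff(profile_markers(B), bb)
  clash <- intersect(a_spec, b_spec)
  if (length(clash)) {
    stop("non-backbone marker(s) present in both profiles: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  ia <- match$pairs$index_a
  ib <- match$pairs$index_b
  merged <- cbind(
    (A$exprs[ia, bb, drop = FALSE] + B$exprs[ib, bb, drop = FALSE]) / 2,
    A$exprs[ia, a_spec, drop = FALSE],
    B$exprs[ib, b_spec, drop = FALSE]
  )
  colnames(merged) <- c(bb, a_spec, b_spec)
  out <- cyto_profile(merged, sample_id = A$sample_id,
                      panel_id = paste(A$panel_id, B$panel_id, sep = "+"),
                      transformed = A$transformed || B$transformed)
  attr(out, "provenance") <- cbind(index_a = ia, index_b = ib)
  out
}

#' Merge a set of panel profiles into one high-dimensional profile
#'
#' Sequentially merges the profiles in `order`: the first two panels are
#' matched and merged, then the intermediate (whose backbone columns hold
#' the running average) is matched against the next panel, and so on.
#' Accounting follows the k-profile identity
#' `excluded = sum(inputs) - k * merged`.
#'
#' @param profiles named list of transformed [cyto_profile()] objects (one
#'   per panel) sharing the backbone markers.
#' @param spec a [backbone_spec()].
#' @param order character vector of panel names giving the merge order;
#'   defaults to the list order.
#' @return an object of class `merge_result`: list with `merged` (profile
#'   over the union of markers), `n_input` (named per-panel counts),
#'   `n_merged`, `n_excluded`, and `provenance` (matrix, one column per
#'   input panel, giving each merged cell's source row in that panel).
#' @export
merge_panelset <- function(profiles, spec, order = names(profiles)) {
  if (length(profiles) < 2L) stop("need >= 2 profiles to merge",
                                  call. = FALSE)
  unknown <- setdiff(order, names(profiles))
  if (length(unknown)) {
    stop("unknown panel(s) in order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (p in profiles) {
    missing <- setdiff(spec$markers, profile_markers(p))
    if (length(missing)) {
      stop("profile ", p$panel_id, " lacks backbone marker(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  n_input <- vapply(profiles[order], n_events, integer(1))
  current <- profiles[[order[1]]]
  prov <- matrix(seq_len(n_events(current)), ncol = 1,
                 dimnames = list(NULL, order[1]))
  for (panel in order[-1]) {
    nxt <- profiles[[panel]]
    m <- match_profiles(current, nxt, spec)
    current <- merge_two(current, nxt, m, spec)
    pp <- attr(current, "provenance")
    prov <- cbind(prov[pp[, "index_a"], , drop = FALSE],
                  pp[, "index_b"])
    colnames(prov)[ncol(prov)] <- panel
  }
  n_merged <- n_events(current)
  k <- length(order)
  structure(
    list(merged = current, n_input = n_input, n_merged = n_merged,
         n_excluded = sum(n_input) - k * n_merged, provenance = prov),
    class = "merge_result"
  )
}

#' Excluded-cell accounting for a k-profile merge
#'
#' The number of input cells left out of a merge of `k` profiles:
#' every merged cell consumes one cell from each input, so
#' `excluded = sum(inputs) - k * merged`.
#'
#' @param n_input numeric vector of per-input cell counts.
#' @param n_merged merged cell count.
#' @return excluded cell count.
#' @export
#' @examples
#' merge_accounting(c(237039, 192201, 139218), 139104) # 151146
merge_accounting <- function(n_input, n_merged) {
  sum(n_input) - length(n_input) * n_merged
}

#' Tabulate a merge result
#'
#' One row per input profile with its cell count, plus a combined row with
#' the merged and excluded cell counts; the excluded column is re-derivable
#' from the others via [merge_accounting()]. Serializable as TSV.
#'
#' @param result a `merge_result` from [merge_panelset()].
#' @return data.frame with columns `profile`, `n_cells`, `n_excluded`.
#' @export
merge_report <- function(result) {
  data.frame(
    profile = c(names(result$n_input),
                paste(names(result$n_input), collapse = "+")),
    n_cells = c(unname(result$n_input), result$n_merged),
    n_excluded = c(rep(NA_real_, length(result$n_input)),
                   result$n_excluded),
    stringsAsFactors = FALSE
  )
}

#' Score a merge against synthetic ground truth
#'
#' Fraction of merged cells whose contributing rows across all panels carry
#' the same ground-truth event id (i.e. are copies of the same simulated
#' cell).
#'
#' @param result a `merge_result`.
#' @param panels named list of the input profiles (with `event_ids` set by
#'   [split_panels()]).
#' @return pairing accuracy in `[0, 1]`.
#' @export
matching_accuracy <- function(result, panels) {
  prov <- result$provenance
  if (!nrow(prov)) return(NA_real_)
  ids <- sapply(colnames(prov), function(p) {
    panels[[p]]$event_ids[prov[, p]]
  })
  ids <- matrix(ids, nrow = nrow(prov))
  mean(apply(ids, 1, function(r) length(unique(r)) == 1L))
}
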