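#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero, the
#' convention used when summary cell counts are reported as whole numbers.
#' Base [round()] rounds halves to even, which disagrees on values such as
#' x.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(142264.5) # 142265
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Pairwise Euclidean distances between the rows of A and the rows of B.
# Small problems accumulate per-marker squared differences, making each
# entry arithmetically identical to sqrt(sum((a - b)^2)) computed pairwise
# (exact duplicates give an exact zero, which keeps tie-breaking
# deterministic). Large problems switch to the expanded-square BLAS form,
# clamped at zero against cancellation.
cross_dist <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  na <- nrow(A); nb <- nrow(B)
  if (as.double(na) * nb <= 1e6) {
    D2 <- matrix(0, na, nb)
    for (j in seq_len(ncol(A))) {
      D2 <- D2 + outer(A[, j], B[, j], "-")^2
    }
  } else {
    D2 <- tcrossprod(A, B)
    D2 <- -2 * D2 + rowSums(A^2)          # recycles down columns
    D2 <- sweep(D2, 2, rowSums(B^2), "+")
    D2[D2 < 0] <- 0
  }
  sqrt(D2)
}

# Shared argument check: a positive scalar.
check_positive_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(what, " must be a positive scalar", call. = FALSE)
  }
  invisible(x)
}
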