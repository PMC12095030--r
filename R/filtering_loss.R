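#' Squared Frobenius norm of the feature Gram matrix
#'
#' For a samples x features matrix M, returns \eqn{\|M^\top M\|_F^2}, the sum
#' of squares of all entries of the p x p Gram matrix. This quantity tracks
#' the total covariance carried by the features: each squared inner product
#' between feature columns contributes to it (off-diagonal pairs are counted
#' in both triangles, consistently in numerator and denominator of the
#' filtering-loss ratio).
#'
#' @param counts count tibble or numeric matrix (samples x features).
#' @return non-negative scalar; 0 for an empty matrix.
#' @export
frob_sq_gram <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  if (length(m) == 0) return(0)
  g <- crossprod(m)
  sum(g * g)
}

#' Filtering loss of a decontamination step
#'
#' Quantifies the share of the pre-filter covariance structure removed by
#' filtering: `fl = 1 - ||Y'Y||_F^2 / ||X'X||_F^2`, where X is the
#' pre-filter count matrix and Y the post-filter matrix (whole features
#' removed and/or reads partially removed). Features absent from `post` are
#' treated as zeroed columns, so whole-feature removal and zeroing are
#' equivalent. Values near 0 mean the removed reads carried little
#' covariance; values near 1 are a warning sign of over-filtering.
#'
#' @param pre pre-filter count tibble.
#' @param post post-filter count tibble; its samples must equal `pre`'s and
#'   its features must be a subset of `pre`'s, with `post <= pre`
#'   element-wise (tolerance 1e-9).
#' @return object of class `filtering_loss` with elements `fl`,
#'   `pre_frob_sq`, `post_frob_sq`.
#' @export
filtering_loss <- function(pre, post) {
  x <- count_matrix(pre)
  y0 <- count_matrix(post)
  extra_s <- setdiff(rownames(y0), rownames(x))
  if (length(extra_s)) {
    abort(paste0("Post-filter samples not present pre-filter: ",
                 paste(extra_s, collapse = ", ")))
  }
  if (!setequal(rownames(y0), rownames(x))) {
    abort("Pre- and post-filter tables must cover the same samples.")
  }
  extra_f <- setdiff(colnames(y0), colnames(x))
  if (length(extra_f)) {
    abort(paste0("Post-filter features not present pre-filter: ",
                 paste(extra_f, collapse = ", ")))
  }
  # removed features become zero columns in Y
  y <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  y[rownames(y0), colnames(y0)] <- y0
  if (any(y > x + 1e-9)) {
    abort("Post-filter counts exceed pre-filter counts; arguments may be swapped.")
  }
  pre_f <- frob_sq_gram(x)
  post_f <- frob_sq_gram(y)
  if (pre_f == 0) {
    warn("Pre-filter matrix is all zero; filtering loss defined as 0.")
    fl <- 0
  } else {
    fl <- 1 - post_f / pre_f
  }
  structure(list(fl = fl, pre_frob_sq = pre_f, post_frob_sq = post_f),
            class = "filtering_loss")
}

#' @export
print.filtering_loss <- function(x, ...) {
  cat("Filtering loss: ", format(x$fl, digits = 4),
      "  (removed reads carried ", format(100 * x$fl, digits = 3),
      "% of the pre-filter covariance)\n", sep = "")
  invisible(x)
}

#' Per-feature filtering-loss contributions
#'
#' For each feature, the filtering loss that would result from removing that
#' single feature. Features with values near 1 dominate the covariance
#' structure; removing them risks over-filtering.
#'
#' @param pre count tibble.
#' @return tibble with `feature_id` and `fl_if_removed`, in input feature order.
#' @export
feature_contributions <- function(pre) {
  x <- count_matrix(pre)
  pre_f <- frob_sq_gram(x)
  if (pre_f == 0) {
    return(tibble::tibble(feature_id = colnames(x),
                          fl_if_removed = rep(0, ncol(x))))
  }
  g <- crossprod(x)
  g2 <- g * g
  # zeroing column j removes row j and column j of the Gram matrix;
  # the diagonal cell (j,j) is shared, so subtract it once
  drop_j <- 2 * colSums(g2) - diag(g2)
  tibble::tibble(feature_id = colnames(x),
                 fl_if_removed = unname(drop_j) / pre_f)
}
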