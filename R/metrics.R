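#' Pearson correlation with an explicit zero-variance policy
#'
#' Standard Pearson correlation of two activity vectors. If either vector has
#' zero variance the correlation is undefined; rather than returning a silent
#' 0/0, the function returns `NA_real_` and emits a warning. Spontaneous
#' activity (`s0 > 0`) makes constant output patterns rare in practice.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return The correlation, or `NA_real_` when undefined.
#' @export
pearson <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Pairwise correlation matrix of stimulus representations
#'
#' Computes all pairwise Pearson correlations between the columns of an
#' activity matrix (input patterns or steady-state mitral outputs) and the
#' mean correlation over distinct unordered pairs (diagonal excluded;
#' undefined pairs are excluded from the mean with a warning).
#'
#' @param x A [stimulus_ensemble()], a [solve_steady_state()] result (mitral
#'   activities are used), or a channels-by-stimuli matrix.
#' @return An object of class `correlation_report`: `matrix` (symmetric, unit
#'   diagonal), `mean` and `labels`.
#' @export
correlation_matrix <- function(x) {
  if (inherits(x, "stimulus_ensemble")) {
    mat <- x$patterns; labels <- x$labels
  } else if (inherits(x, "steady_state")) {
    mat <- x$mitral; labels <- x$labels
  } else {
    mat <- as.matrix(x)
    labels <- colnames(mat)
    if (is.null(labels)) labels <- paste0("stimulus_", seq_len(ncol(mat)))
  }
  n <- ncol(mat)
  if (n < 2) stop("need at least two patterns")
  cm <- diag(1, n)
  dimnames(cm) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    cm[i, j] <- cm[j, i] <- pearson(mat[, i], mat[, j])
  off <- cm[upper.tri(cm)]
  if (anyNA(off))
    warning(sum(is.na(off)), " undefined pair(s) excluded from the mean correlation")
  structure(list(matrix = cm, mean = mean(off, na.rm = TRUE), labels = labels),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_report> %d stimuli, mean off-diagonal correlation %.3f\n",
              length(x$labels), x$mean))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Mean pairwise correlation
#'
#' @param x Anything accepted by [correlation_matrix()].
#' @return Mean Pearson correlation over distinct unordered pairs.
#' @export
mean_correlation <- function(x) correlation_matrix(x)$mean

#' Quadrant sums of an effective connectivity matrix
#'
#' Splits the mitral indices into two disjoint groups (e.g. cells dominated by
#' one mixture component versus the other) and sums the off-diagonal synaptic
#' weights within each of the four blocks. The diagonal (self-inhibition) is
#' excluded. Used to compare the lateral inhibition contributed by "mixed"
#' granule cells (off-diagonal blocks) across enrichment protocols.
#'
#' @param W Square connectivity matrix.
#' @param partition List of two disjoint integer index sets covering all rows.
#' @return A 2 x 2 matrix of block sums.
#' @export
quadrant_sums <- function(W, partition) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), length(partition) == 2L)
  idx <- c(partition[[1L]], partition[[2L]])
  if (anyDuplicated(idx)) stop("partition sets overlap")
  if (!setequal(idx, seq_len(nrow(W))))
    stop("partition must cover all mitral indices")
  Woff <- W; diag(Woff) <- 0
  out <- matrix(0, 2, 2, dimnames = list(c("set1", "set2"), c("set1", "set2")))
  for (i in 1:2) for (j in 1:2)
    out[i, j] <- sum(Woff[partition[[i]], partition[[j]], drop = FALSE])
  out
}

#' Display ordering of mitral cells for a reference stimulus pair
#'
#' Deterministic permutation placing cells dominated by the first reference
#' pattern first, cells dominated by the second last, and shared cells in the
#' middle; ties are broken by index. Display-only: no computation in the
#' package depends on this ordering.
#'
#' @param x A [stimulus_ensemble()] or channels-by-stimuli matrix.
#' @param reference_pair Indices of the two reference stimuli.
#' @return An integer permutation of the channel indices.
#' @export
sort_for_display <- function(x, reference_pair = c(1L, 2L)) {
  mat <- if (inherits(x, "stimulus_ensemble")) x$patterns else as.matrix(x)
  stopifnot(length(reference_pair) == 2L, max(reference_pair) <= ncol(mat))
  a <- mat[, reference_pair[1L]]
  b <- mat[, reference_pair[2L]]
  order(b - a, seq_along(a))
}
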