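#' Glomerular activation pattern
#'
#' A single odor stimulus, represented as a nonnegative activation level per
#' input channel (one channel per glomerulus). Patterns are used as-is: no
#' rescaling or normalization is applied by the constructor.
#'
#' @param values Numeric vector of nonnegative, finite activation levels
#'   (arbitrary units), one per channel.
#' @param label Odor identifier.
#' @param grid_shape Optional integer vector `c(rows, cols)` giving the 2-D
#'   layout the pattern was derived from (e.g. by [downsample_max()]).
#' @return An object of class `glomerular_pattern`.
#' @examples
#' p <- glomerular_pattern(c(1, 0.5, 0, 0.2), label = "odor A")
#' p
#' @export
glomerular_pattern <- function(values, label = "stimulus", grid_shape = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("a glomerular pattern needs at least one channel")
  if (!all(is.finite(values)))
    stop("activation levels must be finite")
  if (any(values < 0))
    stop("activation levels must be nonnegative")
  if (!is.null(grid_shape)) {
    grid_shape <- as.integer(grid_shape)
    stopifnot(length(grid_shape) == 2L, prod(grid_shape) == length(values))
  }
  structure(
    list(values = values, label = as.character(label)[1L], grid_shape = grid_shape),
    class = "glomerular_pattern"
  )
}

#' @export
print.glomerular_pattern <- function(x, ...) {
  cat(sprintf("<glomerular_pattern> '%s': %d channels, max %.3g\n",
              x$label, length(x$values), max(x$values)))
  invisible(x)
}

#' Stimulus ensemble
#'
#' An ordered set of glomerular patterns of identical dimension. The ensemble
#' is the unit over which granule-cell resilience is accumulated: one survival
#' assessment sums thresholded activity over every stimulus it contains.
#'
#' @param patterns A list of [glomerular_pattern()] objects, or a numeric
#'   matrix with one column per stimulus (channels in rows).
#' @param labels Optional character vector of stimulus labels.
#' @return An object of class `stimulus_ensemble` holding a channels-by-stimuli
#'   matrix (`$patterns`) and `$labels`.
#' @export
stimulus_ensemble <- function(patterns, labels = NULL) {
  if (is.list(patterns)) {
    if (length(patterns) == 0L) stop("ensemble must be nonempty")
    lens <- vapply(patterns, function(p) length(p$values), integer(1))
    if (length(unique(lens)) != 1L)
      stop("all patterns in an ensemble must have the same number of channels")
    mat <- vapply(patterns, function(p) p$values, numeric(lens[1L]))
    mat <- matrix(mat, nrow = lens[1L])
    if (is.null(labels))
      labels <- vapply(patterns, function(p) p$label, character(1))
  } else {
    mat <- as.matrix(patterns)
    if (ncol(mat) == 0L || nrow(mat) == 0L) stop("ensemble must be nonempty")
    if (is.null(labels)) {
      labels <- colnames(mat)
      if (is.null(labels)) labels <- paste0("stimulus_", seq_len(ncol(mat)))
    }
  }
  if (!all(is.finite(mat)) || any(mat < 0))
    stop("ensemble patterns must be finite and nonnegative")
  stopifnot(length(labels) == ncol(mat))
  colnames(mat) <- labels
  structure(list(patterns = mat, labels = as.character(labels)),
            class = "stimulus_ensemble")
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat(sprintf("<stimulus_ensemble> %d stimuli x %d channels: %s\n",
              ncol(x$patterns), nrow(x$patterns),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

n_stimuli <- function(ensemble) ncol(ensemble$patterns)
n_channels <- function(ensemble) nrow(ensemble$patterns)

#' Down-sample a 2-D activation map by blockwise maxima
#'
#' Reduces a pixel-level activation map (e.g. a 2-deoxyglucose uptake image) to
#' a coarser channel vector by retaining, within each block of adjacent pixels,
#' the highest value rather than the block average. Max-pooling avoids the
#' excessive smoothing of focal activation hot-spots that averaging would
#' cause. Trailing rows/columns that do not fill a complete block are cropped.
#'
#' @param grid Nonnegative numeric matrix (pixels).
#' @param block Integer vector `c(rows, cols)` giving the pooling window; a
#'   single integer is used for both dimensions.
#' @param label Odor identifier for the resulting pattern.
#' @return A [glomerular_pattern()] whose `grid_shape` records the pooled
#'   layout; values are stored column-major over the pooled grid.
#' @export
downsample_max <- function(grid, block, label = "downsampled") {
  grid <- as.matrix(grid)
  if (length(grid) == 0L) stop("empty grid")
  if (!all(is.finite(grid)) || any(grid < 0))
    stop("grid must be finite and nonnegative")
  block <- as.integer(rep(block, length.out = 2L))
  if (any(block < 1L)) stop("block dimensions must be >= 1")
  if (block[1L] > nrow(grid) || block[2L] > ncol(grid))
    stop("block larger than grid")
  nbr <- nrow(grid) %/% block[1L]
  nbc <- ncol(grid) %/% block[2L]
  grid <- grid[seq_len(nbr * block[1L]), seq_len(nbc * block[2L]), drop = FALSE]
  pooled <- matrix(0, nbr, nbc)
  for (i in seq_len(nbr)) {
    rows <- ((i - 1L) * block[1L] + 1L):(i * block[1L])
    for (j in seq_len(nbc)) {
      cols <- ((j - 1L) * block[2L] + 1L):(j * block[2L])
      pooled[i, j] <- max(grid[rows, cols])
    }
  }
  glomerular_pattern(as.vector(pooled), label = label, grid_shape = c(nbr, nbc))
}

#' Two symmetric pairs of highly similar four-channel stimuli
#'
#' Generates the minimal four-stimulus, four-glomerulus caricature of two
#' enantiomer pairs. Stimuli 1 and 2 drive channels 1-2 strongly (levels
#' `a` and `similarity * a`, swapped between the two stimuli) and channels 3-4
#' weakly (level `b`); stimuli 3 and 4 are the mirror image under the channel
#' permutation (1 2 3 4) -> (3 4 1 2). At `similarity = 1` the members of each
#' pair are identical; as `similarity` decreases the within-pair Pearson
#' correlation decreases monotonically.
#'
#' @param similarity Within-pair similarity parameter in `[0, 1]`.
#' @param amplitudes Named numeric vector `c(strong=, weak=)`: the strong
#'   channel level `a` and the weak background level `b` (`a > b >= 0`).
#' @return A [stimulus_ensemble()] of 4 stimuli on 4 channels.
#' @export
generate_symmetric4 <- function(similarity = 1,
                                amplitudes = c(strong = 1, weak = 0.2)) {
  if (!is.numeric(similarity) || length(similarity) != 1L ||
      similarity < 0 || similarity > 1)
    stop("similarity must be a single value in [0, 1]")
  a <- unname(amplitudes["strong"]); b <- unname(amplitudes["weak"])
  if (is.na(a) || is.na(b)) { a <- amplitudes[1L]; b <- amplitudes[2L] }
  if (!(a > b && b >= 0)) stop("require strong > weak >= 0")
  q <- similarity * a
  mat <- cbind(c(a, q, b, b),
               c(q, a, b, b),
               c(b, b, a, q),
               c(b, b, q, a))
  stimulus_ensemble(mat, labels = c("pair1_a", "pair1_b", "pair2_a", "pair2_b"))
}

#' Minimal three-mitral-cell stimulus pair
#'
#' Two stimuli on three channels in which channels 1 and 2 are strongly driven
#' by both stimuli while channel 3 distinguishes them (level `weak` in stimulus
#' 1, silent in stimulus 2). Granule cells connecting the co-active channels
#' 1-2 can then outnumber the other populations and preferentially suppress
#' the shared part of the patterns.
#'
#' @param strong Strong drive level (> 0).
#' @param weak Distinguishing level on channel 3 (`0 <= weak < strong`; at
#'   `weak == strong` stimulus 1 becomes constant and its correlations are
#'   undefined under the zero-variance policy of [pearson()]).
#' @return A [stimulus_ensemble()] of 2 stimuli on 3 channels.
#' @export
generate_toy3 <- function(strong = 1, weak = 0.2) {
  if (strong <= 0) stop("strong level must be positive")
  if (weak < 0 || weak > strong) stop("require 0 <= weak <= strong")
  mat <- cbind(c(strong, strong, weak), c(strong, strong, 0))
  stimulus_ensemble(mat, labels = c("toy_a", "toy_b"))
}

#' Linear mixture of glomerular patterns
#'
#' Mixtures are modelled as linear combinations of the component patterns:
#' glomerular activation of an odor mixture is approximated by
#' `sum_k fraction_k * pattern_k`.
#'
#' @param patterns List of [glomerular_pattern()] objects of equal length, or a
#'   channels-by-components matrix.
#' @param fractions Nonnegative mixing fractions, one per component.
#' @param label Label for the mixture.
#' @return A [glomerular_pattern()].
#' @export
mix_patterns <- function(patterns, fractions, label = "mixture") {
  if (is.list(patterns) && !is.matrix(patterns))
    patterns <- stimulus_ensemble(patterns)$patterns
  patterns <- as.matrix(patterns)
  fractions <- as.numeric(fractions)
  if (length(fractions) != ncol(patterns))
    stop("need one fraction per component pattern")
  if (any(fractions < 0) || !all(is.finite(fractions)))
    stop("fractions must be finite and nonnegative")
  glomerular_pattern(drop(patterns %*% fractions), label = label)
}

#' Enriched stimulus ensemble for a given protocol
#'
#' Builds the ensemble presented within one survival-assessment interval when
#' a background odor environment is enriched with extra odors. Under the
#' `alternating` protocol each pure enrichment odor enters the ensemble as a
#' separate stimulus (the granule-cell removal occurs only after the complete
#' set of background and enrichment stimuli has been presented, so all of them
#' contribute to the same resilience sum). Under the `mixture` protocol a
#' single mixed pattern, `mix_patterns(enrichment, fractions)`, is added.
#'
#' @param background A [stimulus_ensemble()].
#' @param enrichment List of [glomerular_pattern()] objects (may be empty).
#' @param protocol `"alternating"` or `"mixture"`.
#' @param fractions Mixing fractions for the mixture protocol (default equal).
#' @param multiplicity How many times the mixed pattern enters the ensemble
#'   (mixture protocol only). The default 1 adds it as a single stimulus;
#'   setting it to the number of components gives both protocols the same
#'   total presentation weight per assessment interval, the matching
#'   condition under which the two protocols are compared.
#' @return A [stimulus_ensemble()].
#' @export
make_enrichment_schedule <- function(background, enrichment,
                                     protocol = c("alternating", "mixture"),
                                     fractions = NULL, multiplicity = 1L) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(background, "stimulus_ensemble"))
  if (length(enrichment) == 0L) return(background)
  if (inherits(enrichment, "glomerular_pattern")) enrichment <- list(enrichment)
  emat <- stimulus_ensemble(enrichment)$patterns
  if (nrow(emat) != n_channels(background))
    stop("enrichment patterns must match the background channel count")
  if (protocol == "alternating") {
    mat <- cbind(background$patterns, emat)
    labels <- c(background$labels, colnames(emat))
  } else {
    if (is.null(fractions)) fractions <- rep(1 / ncol(emat), ncol(emat))
    mixed <- mix_patterns(emat, fractions, label = "enrichment_mixture")
    stopifnot(multiplicity >= 1)
    reps <- matrix(rep(mixed$values, multiplicity), ncol = multiplicity)
    mat <- cbind(background$patterns, reps)
    labels <- c(background$labels,
                paste0("enrichment_mixture",
                       if (multiplicity > 1L) seq_len(multiplicity) else ""))
  }
  stimulus_ensemble(mat, labels = labels)
}

#' Synthetic focal odor ensemble
#'
#' Generates an ensemble emulating the qualitative features of glomerular
#' activation maps: focal nonnegative patterns (sums of narrow Gaussian bumps
#' on a 1-D channel axis) including two highly similar "enantiomer-like"
#' pairs (same bump locations, slightly exchanged amplitudes) and a set of
#' dissimilar background odors. Uses the current RNG state; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n_channels Number of input channels.
#' @param n_background Number of dissimilar background odors.
#' @param n_similar_pairs Number of similar pairs prepended to the ensemble.
#' @param bumps Number of Gaussian foci per odor.
#' @param width Focus width in channels (Gaussian sigma).
#' @param amplitude Peak activation level.
#' @param pair_contrast Amplitude exchange within a similar pair (0 = identical
#'   members; larger values lower the within-pair correlation).
#' @return A [stimulus_ensemble()]; similar pairs occupy the first
#'   `2 * n_similar_pairs` columns.
#' @export
generate_odor_set <- function(n_channels = 96, n_background = 4,
                              n_similar_pairs = 2, bumps = 2, width = 0.4,
                              amplitude = 1, pair_contrast = 0.12) {
  x <- seq_len(n_channels)
  bump <- function(center, amp)
    amp * exp(-((x - center)^2) / (2 * width^2))
  make_odor <- function(amps, centers)
    Reduce(`+`, Map(bump, centers, amps))
  # spread bump centers over well-separated slots so odors stay focal and
  # distinct odors overlap little
  n_slots <- (n_similar_pairs + n_background) * bumps
  slot_width <- n_channels / n_slots
  slots <- sample((seq_len(n_slots) - 0.5) * slot_width +
                    stats::runif(n_slots, -slot_width / 4, slot_width / 4))
  take_slots <- function(k) {
    out <- slots[seq_len(k)]
    slots <<- slots[-seq_len(k)]
    out
  }
  cols <- list(); labels <- character(0)
  for (p in seq_len(n_similar_pairs)) {
    centers <- take_slots(bumps)
    base <- seq(amplitude, amplitude * 0.8, length.out = bumps)
    jit <- pair_contrast * base * rep_len(c(1, -1), bumps)
    cols <- c(cols, list(make_odor(base + jit, centers),
                         make_odor(base - jit, centers)))
    labels <- c(labels, paste0("pair", p, c("_a", "_b")))
  }
  for (k in seq_len(n_background)) {
    centers <- take_slots(bumps)
    amps <- stats::runif(bumps, 0.6, 1) * amplitude
    cols <- c(cols, list(make_odor(amps, centers)))
    labels <- c(labels, paste0("background_", k))
  }
  stimulus_ensemble(matrix(unlist(cols), nrow = n_channels), labels = labels)
}

#' Read a pattern from an image or numeric text file
#'
#' Accepts a grayscale PNG or TIFF image or a whitespace-delimited numeric
#' matrix. Image intensities are used as activation levels directly; any
#' amplitude convention of the source archive is recorded in the label only.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`, or text matrix).
#' @param label Odor identifier (defaults to the file name).
#' @return The activation map as a nonnegative numeric matrix, suitable for
#'   [downsample_max()].
#' @export
read_activation_grid <- function(path, label = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  grid <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG activation maps requires the 'png' package")
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF activation maps requires the 'tiff' package")
      img <- tiff::readTIFF(path)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    },
    as.matrix(utils::read.table(path))
  )
  grid <- unname(as.matrix(grid))
  if (!all(is.finite(grid)) || any(grid < 0))
    stop("activation grid must be finite and nonnegative")
  attr(grid, "label") <- label
  grid
}
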