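# Laplacian pyramids.
#
# Two kernel variants are provided:
#
# * "binomial": the classic construction — reduce blurs with [1 4 6 4 1]/16
#   (replicated borders) and keeps odd rows/columns; expand is the matching
#   polyphase interpolation. Smooth octave band-splitting.
# * "box": reduce takes 2x2 block means and expand replicates each coarse
#   pixel 2x2 (a Haar-style pyramid). Here reduce(expand(c)) = c exactly,
#   every band lies in the null space of reduce, and zeroing whole 2x2-
#   aligned groups of band coefficients is an exact orthogonal projection —
#   the property the foveated filter relies on for idempotence.
#
# In both variants band level l is g_l - expand(reduce(g_l)) and synthesis
# is exact up to floating error.

.BINOMIAL5 <- c(1, 4, 6, 4, 1) / 16

# separable 5-tap convolution along rows then columns, edge-replicated
conv5_sep <- function(m, k = .BINOMIAL5) {
  conv_rows <- function(x) {
    n <- nrow(x)
    idx <- function(i) pmin(pmax(i, 1L), n)
    k[1] * x[idx(seq_len(n) - 2L), , drop = FALSE] +
      k[2] * x[idx(seq_len(n) - 1L), , drop = FALSE] +
      k[3] * x +
      k[4] * x[idx(seq_len(n) + 1L), , drop = FALSE] +
      k[5] * x[idx(seq_len(n) + 2L), , drop = FALSE]
  }
  t(conv_rows(t(conv_rows(m))))
}

pyr_reduce <- function(m, kernel = "binomial") {
  d <- dim(m)
  if (any(d %% 2 != 0)) stop("plane dimensions must be even to reduce")
  if (kernel == "box") {
    ri <- (seq_len(d[1]) - 1L) %/% 2L
    ci <- (seq_len(d[2]) - 1L) %/% 2L
    low <- t(rowsum(t(rowsum(m, ri)), ci)) / 4
    dimnames(low) <- NULL
    low
  } else {
    b <- conv5_sep(m)
    b[seq(1, d[1], by = 2), seq(1, d[2], by = 2), drop = FALSE]
  }
}

# Binomial polyphase expand: coarse sample i sits at fine index 2i-1
# (matching the odd-sample decimation in pyr_reduce). Interior weights equal
# zero-stuffing followed by convolution with twice the binomial kernel;
# edges clamp on the coarse grid so every output pixel's weights sum to 1.
pyr_expand <- function(m, target_dim, kernel = "binomial") {
  if (any(target_dim != 2 * dim(m))) {
    stop("expand target must be exactly twice the coarse dimensions")
  }
  if (kernel == "box") {
    return(m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2),
             drop = FALSE])
  }
  expand_rows <- function(cm) {
    n <- nrow(cm)
    prev <- cm[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
    nxt <- cm[pmin(seq_len(n) + 1L, n), , drop = FALSE]
    up <- matrix(0, 2 * n, ncol(cm))
    up[seq(1, 2 * n, by = 2), ] <- 0.125 * prev + 0.75 * cm + 0.125 * nxt
    up[seq(2, 2 * n, by = 2), ] <- 0.5 * cm + 0.5 * nxt
    up
  }
  t(expand_rows(t(expand_rows(m))))
}

#' Build a Laplacian pyramid
#'
#' @param plane Numeric matrix; both dimensions must be divisible by
#'   `2^levels`.
#' @param levels Number of band-pass levels (>= 1). Level 1 of `bands` is
#'   the finest (peak frequency at the image Nyquist), followed by
#'   octave-spaced coarser bands and a low-pass residual.
#' @param kernel `"binomial"` (default, classic 5-tap construction) or
#'   `"box"` (Haar-style 2x2 mean/replicate; see [apply_foveated_filter()]).
#' @return Object of class `laplacian_pyramid`: list with `bands` (list of
#'   matrices, fine to coarse), `lowpass`, `levels` and `kernel`.
#' @export
build_pyramid <- function(plane, levels, kernel = c("binomial", "box")) {
  kernel <- match.arg(kernel)
  stopifnot(is.matrix(plane), levels >= 1)
  d <- dim(plane)
  if (any(d %% (2^levels) != 0) || any(d / 2^levels < 1)) {
    stop("plane dimensions must be divisible by 2^levels (and stay >= 1)")
  }
  bands <- vector("list", levels)
  g <- plane
  for (l in seq_len(levels)) {
    g_next <- pyr_reduce(g, kernel)
    bands[[l]] <- g - pyr_expand(g_next, dim(g), kernel)
    g <- g_next
  }
  structure(list(bands = bands, lowpass = g, levels = levels,
                 kernel = kernel),
            class = "laplacian_pyramid")
}

#' Reconstruct a plane from a Laplacian pyramid
#'
#' Exact synthesis: starting at the low-pass residual, repeatedly expand and
#' add the next finer band.
#'
#' @param pyramid A `laplacian_pyramid`.
#' @return Numeric matrix.
#' @export
reconstruct_pyramid <- function(pyramid) {
  stopifnot(inherits(pyramid, "laplacian_pyramid"))
  g <- pyramid$lowpass
  for (l in rev(seq_len(pyramid$levels))) {
    g <- pyr_expand(g, dim(pyramid$bands[[l]]), pyramid$kernel) +
      pyramid$bands[[l]]
  }
  g
}

#' Peak spatial frequency of a pyramid band
#'
#' Band level `l` (1-based; level 1 is the finest) peaks at the image
#' Nyquist frequency divided by `2^(l-1)`:
#' `(nominal_ppd / 2) / 2^(l-1)` cycles per degree.
#'
#' @param level Band level, 1-based.
#' @param nominal_ppd Display resolution in pixels per degree.
#' @return Peak frequency in cpd.
#' @export
band_peak_frequency <- function(level, nominal_ppd) {
  stopifnot(all(level >= 1), nominal_ppd > 0)
  (nominal_ppd / 2) / 2^(level - 1)
}
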