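#' @useDynLib fdacnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Circular shifts that move the DC sample to/from the matrix center.
# For even n, fftshift and ifftshift coincide; for odd n they differ.
fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq(floor(h / 2) + 1L, h), seq_len(floor(h / 2))),
    c(seq(floor(w / 2) + 1L, w), seq_len(floor(w / 2)))]
}

ifftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c(seq(ceiling(h / 2) + 1L, h), seq_len(ceiling(h / 2))),
    c(seq(ceiling(w / 2) + 1L, w), seq_len(ceiling(w / 2)))]
}

# Row/column index of the DC sample under the centered convention.
dc_index <- function(n) floor(n / 2) + 1L

#' Centered orthonormal 2D Fourier transforms
#'
#' `forward_fft()` maps a real magnitude image to its k-space representation
#' with the DC component at the matrix center; `inverse_fft()` maps a centered
#' k-space back to the image domain and returns the magnitude image (the
#' de-aliasing network consumes magnitude, not phase). Both use orthonormal
#' scaling (division by `sqrt(H * W)`), so Parseval's identity holds exactly:
#' the sum of squared image intensities equals the sum of squared k-space
#' moduli.
#'
#' @param image real numeric matrix (H x W), the artifact-free image.
#' @param kspace complex (or numeric) matrix (H x W), DC at the center.
#' @return `forward_fft()`: a complex H x W matrix; `inverse_fft()`: a real
#'   H x W magnitude matrix.
#' @examples
#' x <- matrix(runif(64 * 64), 64)
#' k <- forward_fft(x)
#' max(abs(inverse_fft(k) - x)) # round-trip, ~1e-15
#' @export
forward_fft <- function(image) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("forward_fft: image contains non-finite values")
  fftshift2(stats::fft(ifftshift2(image))) / sqrt(length(image))
}

#' @rdname forward_fft
#' @export
inverse_fft <- function(kspace) {
  kspace <- as.matrix(kspace)
  if (!all(is.finite(Re(kspace))) || !all(is.finite(Im(kspace))))
    stop("inverse_fft: k-space contains non-finite values")
  Mod(fftshift2(stats::fft(ifftshift2(kspace), inverse = TRUE)) / sqrt(length(kspace)))
}

# inverse transform keeping the complex field (internal; magnitude is the
# public contract)
inverse_fft_complex <- function(kspace) {
  fftshift2(stats::fft(ifftshift2(as.matrix(kspace)), inverse = TRUE)) /
    sqrt(length(kspace))
}

round_half_up <- function(x) floor(x + 0.5)

#' Specify a Cartesian under-sampling mask
#'
#' Bundles the parameters of the three supported retrospective under-sampling
#' patterns. `kind` selects the pattern:
#' \describe{
#'   \item{`"mcp"`}{mixed center-periphery under-sampling (MCP-US): a line
#'     mask that deterministically keeps a contiguous block of central
#'     (low-frequency) lines and the outermost (high-frequency) edge lines,
#'     and fills the rest of the budget with lines drawn uniformly at random
#'     from the band in between. At sampling rate r the budget splits as
#'     r/2 center, r/4 periphery, r/4 random, i.e. 50%/25%/25% of the kept
#'     lines.}
#'   \item{`"1dg"`}{1D Gaussian line mask: phase-encode lines drawn without
#'     replacement with probability proportional to a Gaussian centered on
#'     DC; the DC line is always kept.}
#'   \item{`"2dg"`}{2D Gaussian point mask: individual k-space samples drawn
#'     without replacement under an isotropic Gaussian density centered on
#'     DC; the DC sample is always kept.}
#' }
#'
#' @param kind one of `"mcp"`, `"1dg"`, `"2dg"`.
#' @param sampling_rate fraction of k-space kept, in (0, 1]. 0.20 corresponds
#'   to an acceleration factor of 5.
#' @param image_size side length N of the (square) k-space grid.
#' @param axis for line masks, whether sampled lines are `"columns"`
#'   (vertical lines) or `"rows"`.
#' @param gaussian_sd spread of the Gaussian variants as a fraction of N.
#' @param seed integer seed for the random component.
#' @return an object of class `mask_spec`.
#' @export
mask_spec <- function(kind = c("mcp", "1dg", "2dg"), sampling_rate = 0.2,
                      image_size = 256L, axis = c("columns", "rows"),
                      gaussian_sd = 0.15, seed = 1L) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  if (!(sampling_rate > 0 && sampling_rate <= 1))
    stop("mask_spec: sampling_rate must be in (0, 1]")
  if (gaussian_sd <= 0) stop("mask_spec: gaussian_sd must be > 0")
  if (image_size < 32) stop("mask_spec: image_size must be >= 32")
  structure(list(kind = kind, sampling_rate = sampling_rate,
                 image_size = as.integer(image_size), axis = axis,
                 gaussian_sd = gaussian_sd, seed = as.integer(seed)),
            class = "mask_spec")
}

#' Generate an under-sampling mask
#'
#' Realizes a [mask_spec()] as a binary H x W matrix (1 = sampled) together
#' with composition bookkeeping. For the MCP pattern the counts satisfy
#' S = s_c + s_p + s_r exactly, where S is the total number of kept lines,
#' s_c the central block, s_p the periphery lines (split across both edges,
#' any odd extra on the low-index edge) and s_r the random middle-band lines.
#' Component counts use round-half-up on (r/2)N and (r/4)N with the random
#' component absorbing the remainder, so the total is always round(rN).
#'
#' @param spec a [mask_spec()].
#' @return an object of class `sampling_mask`: a list with elements `matrix`
#'   (binary), `kind`, `axis`, `counts` (named vector `S`, `s_c`, `s_p`,
#'   `s_r`; line masks only), `seed`.
#' @examples
#' m <- make_mask(mask_spec("mcp", 0.2, 64, seed = 3))
#' m$counts
#' @export
make_mask <- function(spec) {
  stopifnot(inherits(spec, "mask_spec"))
  N <- spec$image_size
  rate <- spec$sampling_rate
  n_total <- as.integer(round_half_up(rate * N))
  dc <- dc_index(N)

  if (spec$kind == "2dg") {
    n_pts <- n_total * N
    ii <- rep(seq_len(N), times = N)
    jj <- rep(seq_len(N), each = N)
    s2 <- (spec$gaussian_sd * N)^2
    w <- exp(-((ii - dc)^2 + (jj - dc)^2) / (2 * s2))
    dc_lin <- (dc - 1L) * N + dc
    keep <- dc_lin
    if (n_pts > 1L) {
      pool <- setdiff(seq_len(N * N), dc_lin)
      keep <- c(dc_lin, with_seed(spec$seed, sample(pool, n_pts - 1L, prob = w[pool])))
    }
    mat <- matrix(0, N, N)
    mat[keep] <- 1
    return(structure(list(matrix = mat, kind = spec$kind, axis = spec$axis,
                          counts = c(S = n_pts, s_c = NA, s_p = NA, s_r = NA),
                          seed = spec$seed, spec = spec),
                     class = "sampling_mask"))
  }

  if (spec$kind == "mcp") {
    n_c <- as.integer(round_half_up(rate / 2 * N))
    n_p <- as.integer(round_half_up(rate / 4 * N))
    n_r <- n_total - n_c - n_p
    if (n_c < 1L)
      stop("make_mask: sampling_rate too small, central block is empty")
    # even-length center block puts its extra line on the low-index side
    center <- seq.int(dc - floor(n_c / 2), dc + ceiling(n_c / 2) - 1L)
    p_lo_n <- ceiling(n_p / 2)
    p_hi_n <- floor(n_p / 2)
    periph <- c(seq_len(p_lo_n), if (p_hi_n > 0) seq.int(N - p_hi_n + 1L, N))
    pool <- seq.int(p_lo_n + 1L, N - p_hi_n)
    pool <- setdiff(pool, center)
    if (n_r < 0L || length(pool) < n_r)
      stop("make_mask: random pool smaller than the random budget")
    rnd <- if (n_r > 0) with_seed(spec$seed, sample(pool, n_r)) else integer(0)
    lines <- sort(unique(c(center, periph, rnd)))
    counts <- c(S = length(lines), s_c = n_c, s_p = n_p, s_r = n_r)
  } else { # 1dg line mask
    p <- stats::dnorm(seq_len(N), mean = dc, sd = spec$gaussian_sd * N)
    others <- setdiff(seq_len(N), dc)
    lines <- dc
    if (n_total > 1L)
      lines <- c(dc, with_seed(spec$seed,
                               sample(others, n_total - 1L, prob = p[others])))
    lines <- sort(lines)
    counts <- c(S = length(lines), s_c = NA, s_p = NA, s_r = NA)
  }

  mat <- matrix(0, N, N)
  if (spec$axis == "columns") mat[, lines] <- 1 else mat[lines, ] <- 1
  structure(list(matrix = mat, kind = spec$kind, axis = spec$axis,
                 counts = counts, lines = lines, seed = spec$seed, spec = spec),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> kind=%s  %dx%d  ones=%.1f%%\n",
              x$kind, nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix)))
  if (!is.na(x$counts["s_c"]))
    cat(sprintf("  S=%d  s_c=%d  s_p=%d  s_r=%d\n", x$counts["S"],
                x$counts["s_c"], x$counts["s_p"], x$counts["s_r"]))
  invisible(x)
}

#' Retrospectively under-sample a k-space
#'
#' Element-wise product of the k-space with the binary mask; entries the mask
#' does not keep become exactly zero.
#'
#' @param kspace complex H x W matrix, DC centered.
#' @param mask a `sampling_mask` (or a bare binary matrix of the same shape).
#' @return complex H x W matrix.
#' @export
apply_mask <- function(kspace, mask) {
  m <- if (inherits(mask, "sampling_mask")) mask$matrix else mask
  if (!all(dim(kspace) == dim(m)))
    stop("apply_mask: k-space and mask shapes differ")
  kspace * m
}

#' Zero-filled reconstruction
#'
#' Inverse Fourier transform of the under-sampled k-space with missing entries
#' left at zero: the classical aliased reconstruction that the de-aliasing
#' network takes as input.
#'
#' @inheritParams apply_mask
#' @return real H x W magnitude image (the aliased estimate).
#' @export
zero_filled_recon <- function(kspace, mask) {
  inverse_fft(apply_mask(kspace, mask))
}
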