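#' Specify a synthetic brain-like phantom
#'
#' Parameters of the seeded ellipse-composite phantom generator. Phantoms are
#' Shepp-Logan-like: a skull-like outer ellipse enclosing `n_ellipses`
#' randomized piecewise-constant sub-structures, lightly smoothed so the
#' object is approximately band-limited, with optional additive Gaussian
#' noise. They stand in for real T1/T2 brain slices when exercising the
#' masking, training and evaluation pipeline.
#'
#' @param image_size pixels per side; must be a power of two and >= 32 so
#'   that five levels of 2x pooling inside the network are exact. Default 256
#'   (64 is convenient for fast tests).
#' @param n_ellipses number of randomized internal structures.
#' @param intensity_range range the tissue intensities are drawn from,
#'   within [0, 1].
#' @param noise_sd standard deviation of additive Gaussian noise, in image
#'   units (images are clipped back to [0, 1] afterwards).
#' @param smooth_sd standard deviation (pixels) of the Gaussian blur applied
#'   to the piecewise-constant composite.
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L, n_ellipses = 8L,
                         intensity_range = c(0.15, 1), noise_sd = 0.01,
                         smooth_sd = 1.2, seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 32L || bitwAnd(image_size, image_size - 1L) != 0L)
    stop("phantom_spec: image_size must be a power of two and >= 32")
  if (length(intensity_range) != 2L || any(intensity_range < 0) ||
      any(intensity_range > 1) || diff(intensity_range) < 0)
    stop("phantom_spec: intensity_range must be an increasing pair in [0, 1]")
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  structure(list(image_size = image_size, n_ellipses = as.integer(n_ellipses),
                 intensity_range = as.numeric(intensity_range),
                 noise_sd = noise_sd, smooth_sd = smooth_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Fill an ellipse (normalized [-1,1] coordinates) with a constant intensity.
# xx, yy: coordinate matrices; img modified by overwrite inside the region.
fill_ellipse <- function(img, xx, yy, cx, cy, a, b, theta, value) {
  ct <- cos(theta); st <- sin(theta)
  xr <- (xx - cx) * ct + (yy - cy) * st
  yr <- -(xx - cx) * st + (yy - cy) * ct
  img[(xr / a)^2 + (yr / b)^2 <= 1] <- value
  img
}

# Periodic Gaussian blur via the package's own centered FFT pair. The blur is
# only a band-limiting touch-up, so periodic boundary handling is fine: the
# phantom is zero near the border.
gaussian_blur_fft <- function(img, sd_px) {
  if (sd_px <= 0) return(img)
  n <- nrow(img)
  d <- seq_len(n) - dc_index(n)
  k1 <- exp(-d^2 / (2 * sd_px^2))
  ker <- outer(k1, k1)
  ker <- ker / sum(ker)
  kf <- stats::fft(ifftshift2(ker))
  Re(stats::fft(stats::fft(img) * kf, inverse = TRUE)) / length(img)
}

#' Generate one phantom image
#'
#' Deterministic for a given (`spec$seed`, `index`) pair: the same arguments
#' always produce a bit-identical image, and different seeds give different
#' phantoms. Intensities are clipped to [0, 1].
#'
#' @param spec a [phantom_spec()].
#' @param index non-negative integer identifying the sample within the seed's
#'   stream (so datasets can be generated lazily and reproducibly).
#' @return a real `image_size` x `image_size` matrix in [0, 1].
#' @examples
#' img <- generate_phantom(phantom_spec(64, seed = 7), index = 3)
#' range(img)
#' @export
generate_phantom <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (index < 0) stop("generate_phantom: index must be >= 0")
  n <- spec$image_size
  co <- (seq_len(n) - (n + 1) / 2) / (n / 2)  # [-1, 1) coordinates
  xx <- matrix(co, n, n)
  yy <- t(xx)
  with_seed(sub_seed(spec$seed, index), {
    img <- matrix(0, n, n)
    # skull-like outer ellipse with mild randomized eccentricity/orientation
    a0 <- stats::runif(1, 0.80, 0.92)
    b0 <- stats::runif(1, 0.80, 0.92)
    th0 <- stats::runif(1, -0.15, 0.15)
    base <- 0.85
    img <- fill_ellipse(img, xx, yy, 0, 0, a0, b0, th0, base)
    if (spec$n_ellipses > 0) {
      for (e in seq_len(spec$n_ellipses)) {
        r <- stats::runif(1, 0, 0.5)
        phi <- stats::runif(1, 0, 2 * pi)
        img <- fill_ellipse(img, xx, yy,
                            cx = r * cos(phi), cy = r * sin(phi),
                            a = stats::runif(1, 0.05, 0.35),
                            b = stats::runif(1, 0.05, 0.35),
                            theta = stats::runif(1, 0, pi),
                            value = stats::runif(1, spec$intensity_range[1],
                                                 spec$intensity_range[2]))
      }
    }
    img <- gaussian_blur_fft(img, spec$smooth_sd)
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    pmin(pmax(img, 0), 1)
  })
}

# Split sizes proportional to 100/30/20 (train/val/test), floor + remainder
# to train, minimum 1 per split. Mirrors the absolute 100/30/20 counts at
# n = 150.
split_sizes <- function(n, prop = c(train = 100, val = 30, test = 20)) {
  if (n < 3L) stop("generate_dataset: need n >= 3 so every split is non-empty")
  p <- prop / sum(prop)
  sz <- floor(n * p)
  sz[sz < 1] <- 1
  sz["train"] <- sz["train"] + (n - sum(sz))
  if (sz["train"] < 1) stop("generate_dataset: split sizes infeasible")
  stats::setNames(as.integer(sz), names(prop))
}

#' Generate a paired phantom dataset
#'
#' Produces `n` (ground-truth image, fully sampled k-space) pairs with
#' train/validation/test split labels. The k-space of each sample is computed
#' with [forward_fft()] from the (noisy, clipped) image, so the image is the
#' single source of truth and the round trip
#' `inverse_fft(kspaces[[i]]) == images[[i]]` holds to numerical tolerance.
#'
#' Default split proportions follow a 100:30:20 train/validation/test scheme
#' rescaled to `n` (floored, remainder to train, at least 1 per split);
#' explicit absolute counts can be given instead via `split_counts`.
#'
#' @param n number of samples (>= 3).
#' @param spec a [phantom_spec()].
#' @param split_counts optional integer vector `c(train, val, test)` summing
#'   to `n`, overriding the proportional rule.
#' @return an object of class `phantom_dataset`: list with `images` (list of
#'   matrices), `kspaces` (list of complex matrices), `split` (factor), and
#'   `spec`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), split_counts = NULL) {
  n <- as.integer(n)
  if (is.null(split_counts)) {
    sz <- split_sizes(n)
  } else {
    sz <- stats::setNames(as.integer(split_counts), c("train", "val", "test"))
    if (sum(sz) != n || any(sz < 1))
      stop("generate_dataset: split_counts must be positive and sum to n")
  }
  images <- lapply(seq_len(n) - 1L, function(i) generate_phantom(spec, i))
  kspaces <- lapply(images, forward_fft)
  split <- factor(rep(c("train", "val", "test"), times = sz),
                  levels = c("train", "val", "test"))
  structure(list(images = images, kspaces = kspaces, split = split, spec = spec),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d samples of %dx%d (train/val/test = %s)\n",
              length(x$images), x$spec$image_size, x$spec$image_size,
              paste(table(x$split), collapse = "/")))
  invisible(x)
}

#' Generate a phantom volume with a through-plane content profile
#'
#' Emulates a stack of axial slices through a head: slices near the ends of
#' the stack intersect little tissue, so their phantoms shrink (elliptical
#' cross-section of an ellipsoid), while noise stays constant across slices.
#' Useful for slice-profile analyses where low-content edge slices behave
#' differently from content-rich central ones.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of slices in the stack.
#' @return list of `n_slices` image matrices.
#' @export
generate_volume <- function(spec, n_slices = 20L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_slices <- as.integer(n_slices)
  lapply(seq_len(n_slices), function(s) {
    # sphere cross-section profile: the stack covers the full field of
    # view, extending well past the head as an axial acquisition does, so
    # slices near the stack ends are essentially pure noise while central
    # slices are tissue-rich
    z <- 1.4 * ((2 * s - 1) / n_slices - 1)
    scale <- sqrt(max(1 - z^2, 0.01))
    sp <- spec
    img <- with_scaled_phantom(sp, s - 1L, scale)
    img
  })
}

# Internal: phantom whose ellipse radii and contrast shrink by `scale`.
with_scaled_phantom <- function(spec, index, scale) {
  n <- spec$image_size
  co <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  xx <- matrix(co, n, n)
  yy <- t(xx)
  with_seed(sub_seed(spec$seed, index), {
    img <- matrix(0, n, n)
    a0 <- stats::runif(1, 0.80, 0.92) * scale
    b0 <- stats::runif(1, 0.80, 0.92) * scale
    th0 <- stats::runif(1, -0.15, 0.15)
    img <- fill_ellipse(img, xx, yy, 0, 0, a0, b0, th0, 0.85 * scale)
    if (spec$n_ellipses > 0) {
      for (e in seq_len(spec$n_ellipses)) {
        r <- stats::runif(1, 0, 0.5) * scale
        phi <- stats::runif(1, 0, 2 * pi)
        img <- fill_ellipse(img, xx, yy, r * cos(phi), r * sin(phi),
                            a = stats::runif(1, 0.05, 0.35) * scale,
                            b = stats::runif(1, 0.05, 0.35) * scale,
                            theta = stats::runif(1, 0, pi),
                            value = scale * stats::runif(1,
                                                         spec$intensity_range[1],
                                                         spec$intensity_range[2]))
      }
    }
    img <- gaussian_blur_fft(img, spec$smooth_sd)
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
    pmin(pmax(img, 0), 1)
  })
}

#' Write / read a phantom dataset as plain text
#'
#' Portable text export: one CSV per stored array (image, k-space real part,
#' k-space imaginary part) plus a JSON manifest with the generator spec and
#' split labels. `write_dataset_png()` additionally dumps 8-bit PNGs of the
#' ground-truth images for visual inspection.
#'
#' @param ds a `phantom_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `phantom_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$images)) {
    data.table::fwrite(data.table::as.data.table(ds$images[[i]]),
                       file.path(dir, sprintf("image_%03d.csv", i)), col.names = FALSE)
    data.table::fwrite(data.table::as.data.table(Re(ds$kspaces[[i]])),
                       file.path(dir, sprintf("kreal_%03d.csv", i)), col.names = FALSE)
    data.table::fwrite(data.table::as.data.table(Im(ds$kspaces[[i]])),
                       file.path(dir, sprintf("kimag_%03d.csv", i)), col.names = FALSE)
  }
  jsonlite::write_json(list(n = length(ds$images), split = as.character(ds$split),
                            spec = unclass(ds$spec)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  read_mat <- function(f) as.matrix(data.table::fread(f, header = FALSE))
  n <- man$n
  images <- lapply(seq_len(n), function(i)
    unname(read_mat(file.path(dir, sprintf("image_%03d.csv", i)))))
  kspaces <- lapply(seq_len(n), function(i) {
    re <- unname(read_mat(file.path(dir, sprintf("kreal_%03d.csv", i))))
    im <- unname(read_mat(file.path(dir, sprintf("kimag_%03d.csv", i))))
    re + 1i * im
  })
  spec <- do.call(phantom_spec, man$spec[c("image_size", "n_ellipses",
                                           "intensity_range", "noise_sd",
                                           "smooth_sd", "seed")])
  structure(list(images = images, kspaces = kspaces,
                 split = factor(man$split, levels = c("train", "val", "test")),
                 spec = spec),
            class = "phantom_dataset")
}

#' @rdname write_dataset
#' @export
write_dataset_png <- function(ds, dir) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$images))
    png::writePNG(ds$images[[i]], file.path(dir, sprintf("image_%03d.png", i)))
  invisible(dir)
}
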