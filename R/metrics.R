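# Separable Gaussian filtering with symmetric (half-sample reflect) boundary
# handling, matching the behaviour of standard image-processing libraries so
# metric values are comparable across implementations.
filt1d <- function(M, k, r) {
  n <- nrow(M)
  P <- rbind(M[r:1, , drop = FALSE], M, M[n:(n - r + 1), , drop = FALSE])
  out <- matrix(0, n, ncol(M))
  for (j in seq_len(2 * r + 1))
    out <- out + k[j] * P[j:(j + n - 1), , drop = FALSE]
  out
}

gauss_filt2 <- function(M, sigma, truncate = 4) {
  r <- as.integer(truncate * sigma + 0.5)
  x <- (-r):r
  k <- exp(-0.5 * (x / sigma)^2)
  k <- k / sum(k)
  t(filt1d(t(filt1d(M, k, r)), k, r))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 / MSE)` with the images mapped to the 8-bit scale:
#' intensities are multiplied by `255 / data_max` before the mean squared
#' error is taken, so images on a nominal [0, 1] range (the default) are
#' scored exactly as their 8-bit counterparts. Identical images have zero
#' error; `cap` is returned in that case (the +Inf limit is capped to keep
#' batch averages finite).
#'
#' @param target,recon equal-shaped numeric matrices.
#' @param data_max nominal intensity maximum of the inputs (1 for normalized
#'   images, 255 for 8-bit).
#' @param cap value reported when the MSE is zero.
#' @return PSNR in decibels.
#' @examples
#' psnr(matrix(255, 4, 4), matrix(254, 4, 4), data_max = 255) # ~48.13 dB
#' @export
psnr <- function(target, recon, data_max = 1, cap = Inf) {
  if (!all(dim(target) == dim(recon))) stop("psnr: shape mismatch")
  mse <- mean((255 * (target - recon) / data_max)^2)
  if (mse == 0) return(cap)
  10 * log10(255^2 / mse)
}

#' Structural similarity index
#'
#' Windowed luminance/contrast/structure similarity with Gaussian weighting
#' (sigma 1.5, 11x11 support) and stabilization constants
#' `c1 = (0.01 P)^2`, `c2 = (0.03 P)^2`, where `P = max(T) - min(T)` is the
#' dynamic range of the reference. Local statistics use symmetric boundary
#' padding and sample-covariance normalization, and the half-window border
#' is cropped before averaging, matching standard reference implementations.
#'
#' @param target,recon equal-shaped numeric matrices; the reference `target`
#'   must not be constant (unless both images are identical, which scores 1).
#' @param data_range dynamic range P; defaults to `max(target) - min(target)`.
#' @return similarity score in [-1, 1] (1 for identical images).
#' @export
ssim <- function(target, recon, data_range = NULL) {
  if (!all(dim(target) == dim(recon))) stop("ssim: shape mismatch")
  if (is.null(data_range)) data_range <- max(target) - min(target)
  if (data_range <= 0) {
    if (isTRUE(all.equal(target, recon, tolerance = 0))) return(1)
    stop("ssim: constant reference image (zero dynamic range)")
  }
  sigma <- 1.5; truncate <- 3.5
  r <- as.integer(truncate * sigma + 0.5)
  np <- (2 * r + 1)^2
  cov_norm <- np / (np - 1)
  f <- function(M) gauss_filt2(M, sigma, truncate)
  ux <- f(target); uy <- f(recon)
  vx <- cov_norm * (f(target * target) - ux * ux)
  vy <- cov_norm * (f(recon * recon) - uy * uy)
  vxy <- cov_norm * (f(target * recon) - ux * uy)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  S <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux * ux + uy * uy + c1) * (vx + vy + c2))
  h <- nrow(S); w <- ncol(S)
  mean(S[(r + 1):(h - r), (r + 1):(w - r)])
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the dynamic range of the reference image,
#' `max(T) - min(T)`. Scale-invariant: rescaling both images by a common
#' constant leaves the score unchanged.
#'
#' @param target,recon equal-shaped numeric matrices.
#' @return non-negative score (0 for identical images).
#' @export
nrmse <- function(target, recon) {
  if (!all(dim(target) == dim(recon))) stop("nrmse: shape mismatch")
  rng <- max(target) - min(target)
  if (rng <= 0) stop("nrmse: constant reference image (zero dynamic range)")
  sqrt(mean((target - recon)^2)) / rng
}

#' Pixel-domain visual information fidelity
#'
#' Multi-scale mutual-information quality score: at each of four scales the
#' images are Gaussian-filtered (window shrinking per scale) and, from the
#' second scale on, downsampled by two; local means, variances and
#' covariances feed a scalar-gain-plus-additive-noise model of the
#' distortion channel, and the score is the ratio of the information the
#' distorted image retains about the (Gaussian-modelled) source to the
#' information in the reference, with visual-noise variance
#' `sigma_nsq = 2` on the 8-bit intensity scale. Identical images score 1;
#' the score decreases monotonically with blur and noise.
#'
#' @param target,recon equal-shaped numeric matrices, at least 32 x 32.
#' @param data_max nominal intensity maximum of the inputs (images are
#'   mapped to the 8-bit scale internally, where `sigma_nsq` is calibrated).
#' @param sigma_nsq visual-noise variance of the perception model.
#' @return fidelity score, ~[0, 1] for non-degenerate references.
#' @export
vifp <- function(target, recon, data_max = 1, sigma_nsq = 2) {
  if (!all(dim(target) == dim(recon))) stop("vifp: shape mismatch")
  if (any(dim(target) < 32)) stop("vifp: images must be at least 32x32")
  if (max(target) - min(target) <= 0)
    stop("vifp: constant reference image")
  ref <- target * (255 / data_max)
  dist <- recon * (255 / data_max)
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    sd <- N / 5
    if (scale > 1) {
      ref <- gauss_filt2(ref, sd)[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2)]
      dist <- gauss_filt2(dist, sd)[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2)]
    }
    mu1 <- gauss_filt2(ref, sd); mu2 <- gauss_filt2(dist, sd)
    s1 <- gauss_filt2(ref * ref, sd) - mu1 * mu1
    s2 <- gauss_filt2(dist * dist, sd) - mu2 * mu2
    s12 <- gauss_filt2(ref * dist, sd) - mu1 * mu2
    s1[s1 < 0] <- 0
    s2[s2 < 0] <- 0
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    tiny1 <- s1 < 1e-10
    g[tiny1] <- 0; sv[tiny1] <- s2[tiny1]; s1[tiny1] <- 0
    tiny2 <- s2 < 1e-10
    g[tiny2] <- 0; sv[tiny2] <- 0
    neg <- g < 0
    sv[neg] <- s2[neg]; g[neg] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g * g * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  num / den
}

#' Evaluate a batch of reconstructions
#'
#' Per-image SSIM, PSNR, NRMSE and VIFP against the matching targets, plus
#' their means. PSNR of an exact reconstruction is reported as the capped
#' sentinel `psnr_cap` so averages stay finite.
#'
#' @param targets,recons equal-length lists of equal-shaped matrices.
#' @param labels optional per-image labels (e.g. slice indices).
#' @param data_max nominal intensity maximum (see [psnr()], [vifp()]).
#' @param psnr_cap sentinel PSNR for identical pairs.
#' @return an object of class `metric_report`: list with `per_image` (data
#'   frame) and `means` (named vector).
#' @export
evaluate_batch <- function(targets, recons, labels = NULL, data_max = 1,
                           psnr_cap = 100) {
  if (length(targets) != length(recons))
    stop("evaluate_batch: length mismatch")
  if (is.null(labels)) labels <- seq_along(targets)
  per <- do.call(rbind, lapply(seq_along(targets), function(i) {
    data.frame(label = labels[i],
               ssim = ssim(targets[[i]], recons[[i]]),
               psnr = psnr(targets[[i]], recons[[i]], data_max = data_max,
                           cap = psnr_cap),
               nrmse = nrmse(targets[[i]], recons[[i]]),
               vifp = vifp(targets[[i]], recons[[i]], data_max = data_max))
  }))
  means <- colMeans(per[, c("ssim", "psnr", "nrmse", "vifp")])
  structure(list(per_image = per, means = means), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d images\n", nrow(x$per_image)))
  cat(sprintf("  mean SSIM %.4f  PSNR %.2f dB  NRMSE %.4f  VIFP %.4f\n",
              x$means["ssim"], x$means["psnr"], x$means["nrmse"],
              x$means["vifp"]))
  invisible(x)
}

#' Write a metric report
#'
#' Per-image rows as CSV and the aggregate means as JSON.
#'
#' @param report a `metric_report`.
#' @param csv_path path for the per-image CSV (optional).
#' @param json_path path for the aggregate JSON (optional).
#' @return the report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "metric_report"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(report$means), json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(report)
}
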