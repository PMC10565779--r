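# Synthetic two-channel fluorescence images with known ground truth:
# a MAP2 dendrite mask and VGLUT1 puncta rendered as Gaussian kernels.

#' Ground truth for a synthetic image pair
#'
#' @param map2_mask Logical matrix: the dilated dendrite skeleton.
#' @param puncta_centers Two-column matrix of (row, col) puncta positions,
#'   on or near the mask.
#' @param puncta_intensity Peak intensity per punctum (arbitrary units, > 0).
#' @param background_sd Additive Gaussian noise SD (arbitrary units).
#' @return An object of class \code{"image_truth"}.
#' @export
image_truth <- function(map2_mask, puncta_centers,
                        puncta_intensity = 100, background_sd = 2) {
  stopifnot(is.logical(map2_mask), is.matrix(map2_mask),
            puncta_intensity > 0, background_sd >= 0)
  puncta_centers <- matrix(as.numeric(puncta_centers), ncol = 2)
  structure(list(map2_mask = map2_mask, puncta_centers = puncta_centers,
                 puncta_intensity = puncta_intensity,
                 background_sd = background_sd),
            class = "image_truth")
}

# binary dilation with a (2r+1)-square structuring element, via shifts
.dilate <- function(mask, r) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    sr <- max(1, 1 + dy):min(nr, nr + dy)
    tr <- max(1, 1 - dy):min(nr, nr - dy)
    sc <- max(1, 1 + dx):min(nc, nc + dx)
    tc <- max(1, 1 - dx):min(nc, nc - dx)
    out[tr, tc] <- out[tr, tc] | mask[sr, sc]
  }
  out
}

#' Generate a random dendrite mask with puncta ground truth
#'
#' Draws a few smooth random-walk branches across the field, dilates them
#' into dendrite-like ribbons, and scatters puncta centers onto the mask.
#'
#' @param shape Image shape (rows, cols), at least 64 x 64.
#' @param n_branches Number of dendrite branches.
#' @param n_puncta Number of VGLUT1 puncta.
#' @param thickness Dilation radius (pixels).
#' @param seed Integer seed.
#' @param puncta_intensity,background_sd Passed to \code{\link{image_truth}}.
#' @return An \code{\link{image_truth}}.
#' @export
make_image_truth <- function(shape = c(128, 128), n_branches = 3,
                             n_puncta = 50, thickness = 2, seed = 1L,
                             puncta_intensity = 100, background_sd = 2) {
  stopifnot(all(shape >= 64))
  with_seed(seed, {
    mask <- matrix(FALSE, shape[1], shape[2])
    for (b in seq_len(n_branches)) {
      y <- stats::runif(1, 10, shape[1] - 10)
      x <- stats::runif(1, 10, shape[2] - 10)
      ang <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(round(1.2 * max(shape)))) {
        yi <- round(y); xi <- round(x)
        if (yi < 1 || yi > shape[1] || xi < 1 || xi > shape[2]) break
        mask[yi, xi] <- TRUE
        ang <- ang + stats::rnorm(1, 0, 0.15)
        y <- y + sin(ang); x <- x + cos(ang)
      }
    }
    mask <- .dilate(mask, thickness)
    on_mask <- which(mask, arr.ind = TRUE)
    centers <- on_mask[sample.int(nrow(on_mask), min(n_puncta, nrow(on_mask))),
                       , drop = FALSE]
    image_truth(mask, centers, puncta_intensity, background_sd)
  })
}

#' Render a synthetic VGLUT1/MAP2 image pair
#'
#' MAP2 channel: the dendrite mask at a fixed intensity plus noise. VGLUT1
#' channel: Gaussian puncta at the ground-truth centers plus noise. The
#' returned truth record carries the noiseless channels so the exact
#' above-threshold sums are available for any threshold.
#'
#' @param truth An \code{\link{image_truth}}.
#' @param shape Image shape; must match the mask.
#' @param seed Integer seed for the noise.
#' @param map2_intensity MAP2 intensity on the mask (arbitrary units).
#' @param puncta_sigma Gaussian punctum radius (pixels).
#' @return List of class \code{"image_pair"}: matrices \code{vglut1},
#'   \code{map2}, and \code{truth} (the input record plus
#'   \code{vglut1_clean}, \code{map2_clean}).
#' @export
synthesize_image_pair <- function(truth, shape = dim(truth$map2_mask),
                                  seed = 1L, map2_intensity = 50,
                                  puncta_sigma = 1.5) {
  stopifnot(inherits(truth, "image_truth"),
            identical(as.integer(shape), as.integer(dim(truth$map2_mask))),
            all(shape >= 64))
  nr <- shape[1]; nc <- shape[2]
  vclean <- matrix(0, nr, nc)
  r <- ceiling(4 * puncta_sigma)
  if (nrow(truth$puncta_centers) > 0) {
    for (k in seq_len(nrow(truth$puncta_centers))) {
      cy <- truth$puncta_centers[k, 1]; cx <- truth$puncta_centers[k, 2]
      ys <- max(1, round(cy) - r):min(nr, round(cy) + r)
      xs <- max(1, round(cx) - r):min(nc, round(cx) + r)
      ker <- outer(ys, xs, function(y, x)
        exp(-((y - cy)^2 + (x - cx)^2) / (2 * puncta_sigma^2)))
      vclean[ys, xs] <- vclean[ys, xs] + truth$puncta_intensity * ker
    }
  }
  mclean <- matrix(0, nr, nc)
  mclean[truth$map2_mask] <- map2_intensity
  out <- with_seed(seed, list(
    vglut1 = vclean + matrix(rnorm(nr * nc, 0, truth$background_sd), nr, nc),
    map2 = mclean + matrix(rnorm(nr * nc, 0, truth$background_sd), nr, nc)))
  out$truth <- truth
  out$truth$vglut1_clean <- vclean
  out$truth$map2_clean <- mclean
  class(out) <- "image_pair"
  out
}

#' Write a synthetic image pair as TIFF files
#'
#' @param image An \code{"image_pair"}.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of the two paths (VGLUT1, MAP2).
#' @export
write_image_pair <- function(image, dir, prefix = "synthetic") {
  scale <- max(image$vglut1, image$map2, 1)
  pv <- file.path(dir, paste0(prefix, "_vglut1.tif"))
  pm <- file.path(dir, paste0(prefix, "_map2.tif"))
  tiff::writeTIFF(pmax(image$vglut1, 0) / scale, pv, bits.per.sample = 16)
  tiff::writeTIFF(pmax(image$map2, 0) / scale, pm, bits.per.sample = 16)
  c(pv, pm)
}
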