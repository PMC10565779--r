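# Molecular quantifications: relative expression by 2^-ddCq, Western-blot
# densitometry ratios, threshold-based VGLUT1/MAP2 fluorescence ratios.

#' Relative expression by the 2^-ddCq method
#'
#' Technical replicates are averaged per (sample, gene) on the Cq scale;
#' dCq = Cq_target - Cq_reference per sample; ddCq subtracts the mean dCq of
#' the reference group; the fold change is 2^-ddCq. Assumes 100%
#' amplification efficiency.
#'
#' @param table A \code{data.frame} with columns \code{sample},
#'   \code{group}, \code{gene} (values \code{"target"}/\code{"reference"}),
#'   \code{replicate}, \code{cq} (cycles, in (0, 45)).
#' @param reference_group Group label anchoring ddCq = 0.
#' @return List of class \code{"ddcq_result"}: \code{per_sample}
#'   (sample, group, dcq, ddcq, fold) and \code{per_group}
#'   (group, mean_fold, sem, n).
#' @export
ddcq <- function(table, reference_group) {
  req <- c("sample", "group", "gene", "cq")
  stopifnot(is.data.frame(table), all(req %in% names(table)))
  if (any(table$cq <= 0 | table$cq >= 45))
    stop("Cq values must lie in (0, 45)")
  if (!reference_group %in% table$group)
    stop("empty reference group: ", reference_group)
  # replicate averaging on the Cq scale, before exponentiation
  agg <- stats::aggregate(cq ~ sample + group + gene, table, mean)
  tgt <- agg[agg$gene == "target", ]
  ref <- agg[agg$gene == "reference", ]
  m <- merge(tgt, ref, by = c("sample", "group"),
             suffixes = c("_target", "_reference"))
  if (nrow(m) < length(unique(table$sample)))
    stop("reference gene missing for at least one sample")
  dcq <- m$cq_target - m$cq_reference
  ddcq_val <- dcq - mean(dcq[m$group == reference_group])
  per_sample <- data.frame(sample = m$sample, group = m$group, dcq = dcq,
                           ddcq = ddcq_val, fold = 2^(-ddcq_val))
  per_sample <- per_sample[order(per_sample$group, per_sample$sample), ]
  rownames(per_sample) <- NULL
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
    function(g) data.frame(group = g$group[1], mean_fold = mean(g$fold),
                           sem = stats::sd(g$fold) / sqrt(nrow(g)),
                           n = nrow(g))))
  rownames(per_group) <- NULL
  structure(list(per_sample = per_sample, per_group = per_group,
                 reference_group = reference_group),
            class = "ddcq_result")
}

#' @export
print.ddcq_result <- function(x, ...) {
  cat(sprintf("<ddcq_result> reference group: %s\n", x$reference_group))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}

#' Western-blot densitometry ratios
#'
#' Per-lane ratio of background-corrected target optical density to
#' background-corrected beta-actin density; technical replicates are
#' averaged per sample before any group statistics.
#'
#' @param records A \code{data.frame} with columns \code{lane},
#'   \code{sample}, \code{target_od}, \code{target_background},
#'   \code{actin_od}, \code{actin_background}, and optionally \code{group}.
#' @return List of class \code{"densitometry_result"}: \code{per_lane}
#'   (with \code{ratio}) and \code{per_sample} (mean ratio per sample).
#' @export
densitometry_ratio <- function(records) {
  req <- c("lane", "sample", "target_od", "target_background",
           "actin_od", "actin_background")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  if (any(records$target_background > records$target_od) ||
      any(records$actin_background > records$actin_od))
    stop("background exceeds raw optical density")
  actin_net <- records$actin_od - records$actin_background
  if (any(actin_net <= 0))
    stop("undefined ratio: non-positive net beta-actin density")
  per_lane <- records
  per_lane$ratio <- (records$target_od - records$target_background) / actin_net
  per_sample <- stats::aggregate(ratio ~ sample, per_lane, mean)
  if ("group" %in% names(records)) {
    grp <- stats::aggregate(group ~ sample, per_lane, function(g) g[1])
    per_sample <- merge(per_sample, grp, by = "sample")
  }
  structure(list(per_lane = per_lane, per_sample = per_sample),
            class = "densitometry_result")
}

#' Channel intensity thresholds
#'
#' Records the fluorescence thresholds applied to the VGLUT1 and MAP2
#' channels, with a provenance flag stating whether they were chosen by a
#' blinded observer (the default workflow) or derived automatically.
#'
#' @param vglut1,map2 Non-negative intensity thresholds.
#' @param chosen_blinded Provenance flag.
#' @return An object of class \code{"channel_thresholds"}.
#' @export
channel_thresholds <- function(vglut1, map2, chosen_blinded = TRUE) {
  stopifnot(vglut1 >= 0, map2 >= 0)
  structure(list(vglut1 = vglut1, map2 = map2,
                 chosen_blinded = chosen_blinded),
            class = "channel_thresholds")
}

#' Automatic channel thresholds for testing
#'
#' Sets each channel's threshold just above its background noise ceiling
#' (median + \code{k} times the median absolute deviation). Intended for
#' automated tests; the blinded manual choice remains the reference
#' workflow.
#'
#' @param image A two-channel image (list with \code{vglut1} and
#'   \code{map2} matrices).
#' @param k Multiplier on the MAD (default 6).
#' @return A \code{\link{channel_thresholds}} with
#'   \code{chosen_blinded = FALSE}.
#' @export
auto_thresholds <- function(image, k = 6) {
  ceiling_of <- function(ch) stats::median(ch) + k * stats::mad(ch)
  channel_thresholds(ceiling_of(image$vglut1), ceiling_of(image$map2),
                     chosen_blinded = FALSE)
}

#' VGLUT1/MAP2 fluorescence ratio
#'
#' Total above-threshold VGLUT1 fluorescence intensity normalized to the
#' MAP2 fluorescence area (the count of above-threshold MAP2 pixels), so
#' fields of view with more dendrite are not over-weighted. Only
#' above-threshold pixels enter either quantity, excluding faint background
#' fluorescence.
#'
#' @param image List with numeric matrices \code{vglut1} and \code{map2} of
#'   identical shape (e.g. from \code{\link{synthesize_image_pair}} or
#'   \code{\link{read_image_pair}}).
#' @param thresholds A \code{\link{channel_thresholds}}.
#' @param restrict_to_map2 If TRUE, only VGLUT1 pixels inside the MAP2 mask
#'   are summed (puncta on identified neurites); default FALSE sums all
#'   above-threshold VGLUT1 pixels.
#' @return List of class \code{"vglut_map2_result"}: \code{ratio}
#'   (intensity per pixel of dendrite area), \code{vglut1_sum},
#'   \code{vglut1_pixels}, \code{map2_pixels}, \code{thresholds}.
#' @export
vglut_map2_ratio <- function(image, thresholds,
                             restrict_to_map2 = FALSE) {
  stopifnot(inherits(thresholds, "channel_thresholds"),
            identical(dim(image$vglut1), dim(image$map2)))
  map2_mask <- image$map2 > thresholds$map2
  map2_pixels <- sum(map2_mask)
  if (map2_pixels == 0)
    stop("undefined ratio: no above-threshold MAP2 pixels")
  vmask <- image$vglut1 > thresholds$vglut1
  if (restrict_to_map2) vmask <- vmask & map2_mask
  vsum <- sum(image$vglut1[vmask])
  structure(list(ratio = vsum / map2_pixels, vglut1_sum = vsum,
                 vglut1_pixels = sum(vmask), map2_pixels = map2_pixels,
                 thresholds = thresholds),
            class = "vglut_map2_result")
}

#' Read a two-channel TIFF image pair
#'
#' @param vglut1_path,map2_path Paths to single-channel TIFF files (VGLUT1
#'   and MAP2 channels of the same field of view).
#' @return List with matrices \code{vglut1} and \code{map2}.
#' @export
read_image_pair <- function(vglut1_path, map2_path) {
  v <- tiff::readTIFF(vglut1_path)
  m <- tiff::readTIFF(map2_path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (!identical(dim(v), dim(m))) stop("channel shapes differ")
  list(vglut1 = v, map2 = m)
}
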