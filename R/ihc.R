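#' Two-channel IHC image (CD31 + IgG)
#'
#' Co-stained fluorescence image: a CD31 (endothelial marker) channel and a
#' mouse-IgG channel on the same pixel grid. IgG outside vessels marks
#' blood-brain-barrier leakage.
#'
#' @param cd31,igg numeric intensity matrices of identical size, values
#'   >= 0.
#' @param pixel_size pixel edge length, mm.
#' @return Object of class `two_channel_image`.
#' @export
two_channel_image <- function(cd31, igg, pixel_size = 0.02) {
  stopifnot(is.matrix(cd31), is.matrix(igg))
  if (!identical(dim(cd31), dim(igg))) {
    stopf("invariant violated: channels must share dimensions (%s vs %s)",
          paste(dim(cd31), collapse = "x"), paste(dim(igg), collapse = "x"))
  }
  if (any(cd31 < 0) || any(igg < 0)) {
    stopf("invariant violated: channel intensities must be >= 0")
  }
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(list(cd31 = cd31, igg = igg, pixel_size = pixel_size),
            class = "two_channel_image")
}

#' Labeled rectangular ROI set
#'
#' Rectangular regions of interest with a region label each, as placed by
#' the analyst on an IHC section (`infarct` / `penumbra` / `healthy`) or a
#' homing scan (`ischemic` / `healthy`). Coordinates are 1-based pixel
#' positions of the top-left corner.
#'
#' @param rois data frame with columns `label`, `row`, `col`, `height`,
#'   `width` (pixels).
#' @param require_equal_area require all ROIs to share one area (the homing
#'   convention: every ROI 1 mm^2).
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(rois, require_equal_area = FALSE) {
  needed <- c("label", "row", "col", "height", "width")
  if (!is.data.frame(rois) || !all(needed %in% names(rois))) {
    stopf("rois must be a data frame with columns %s",
          paste(needed, collapse = ", "))
  }
  if (any(rois$height < 1) || any(rois$width < 1) ||
      any(rois$row < 1) || any(rois$col < 1)) {
    stopf("invariant violated: ROI positions and sizes must be >= 1")
  }
  areas <- rois$height * rois$width
  if (require_equal_area && length(unique(areas)) != 1L) {
    stopf("invariant violated: all ROIs must have identical area (got %s px)",
          paste(unique(areas), collapse = ", "))
  }
  rownames(rois) <- NULL
  structure(list(rois = rois, equal_area = require_equal_area),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  tab <- table(x$rois$label)
  cat(sprintf("<roi_set> %d ROIs (%s)\n", nrow(x$rois),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

check_rois_within <- function(rois, dim_img) {
  df <- rois$rois
  for (i in seq_len(nrow(df))) {
    if (df$row[i] + df$height[i] - 1L > dim_img[1] ||
        df$col[i] + df$width[i] - 1L > dim_img[2]) {
      stopf("ROI %d ('%s' at row %d, col %d, %dx%d) extends outside the %dx%d image",
            i, df$label[i], df$row[i], df$col[i], df$height[i], df$width[i],
            dim_img[1], dim_img[2])
    }
  }
  invisible(TRUE)
}

roi_slice <- function(img, df, i) {
  img[df$row[i]:(df$row[i] + df$height[i] - 1L),
      df$col[i]:(df$col[i] + df$width[i] - 1L)]
}

#' Threshold one stain channel into a positive-area mask
#'
#' Global fixed threshold, to be held constant across every image of a study
#' batch ("same settings"): pixels strictly above the threshold count as
#' stained.
#'
#' @param image intensity matrix or a [two_channel_image()].
#' @param channel `"cd31"` or `"igg"` when `image` is two-channel.
#' @param threshold intensity threshold (>= 0).
#' @return Logical matrix of positive pixels.
#' @export
threshold_channel <- function(image, channel = c("cd31", "igg"),
                              threshold = 0.5) {
  if (inherits(image, "two_channel_image")) {
    channel <- match.arg(channel)
    image <- image[[channel]]
  }
  stopifnot(is.matrix(image))
  check_number(threshold, "threshold", lower = 0)
  image > threshold
}

#' Positive-stain areas per ROI
#'
#' Counts positive pixels of each channel mask inside every ROI and converts
#' the counts to mm^2. ROIs with the same region label are averaged within a
#' section to give that region's CD31 and IgG areas.
#'
#' @param cd31_mask,igg_mask logical matrices from [threshold_channel()].
#' @param rois a [roi_set()].
#' @param pixel_size mm per pixel.
#' @return Object of class `area_quant`: `per_roi` (one row per ROI) and
#'   `per_region` (ROI-averaged CD31/IgG areas per region label, mm^2).
#' @export
quantify_rois <- function(cd31_mask, igg_mask, rois, pixel_size = 0.02) {
  stopifnot(is_logical_matrix(cd31_mask), is_logical_matrix(igg_mask),
            inherits(rois, "roi_set"))
  if (!identical(dim(cd31_mask), dim(igg_mask))) {
    stopf("channel masks must share dimensions")
  }
  check_rois_within(rois, dim(cd31_mask))
  df <- rois$rois
  px2 <- pixel_size^2
  per_roi <- data.frame(
    roi = seq_len(nrow(df)), region = df$label,
    roi_area_mm2 = df$height * df$width * px2,
    cd31_area_mm2 = vapply(seq_len(nrow(df)), function(i)
      sum(roi_slice(cd31_mask, df, i)) * px2, numeric(1)),
    igg_area_mm2 = vapply(seq_len(nrow(df)), function(i)
      sum(roi_slice(igg_mask, df, i)) * px2, numeric(1)))
  per_region <- do.call(rbind, lapply(split(per_roi, per_roi$region),
                                      function(g) data.frame(
    region = g$region[1], n_rois = nrow(g),
    cd31_area_mm2 = mean(g$cd31_area_mm2),
    igg_area_mm2 = mean(g$igg_area_mm2))))
  rownames(per_region) <- NULL
  structure(list(per_roi = per_roi, per_region = per_region,
                 pixel_size = pixel_size),
            class = "area_quant")
}

#' @export
print.area_quant <- function(x, ...) {
  cat("<area_quant>\n")
  print(x$per_region)
  invisible(x)
}

#' IgG extravasation ratios, normalized to the healthy region
#'
#' For each section and region, the extravasation ratio is the IgG-stained
#' area divided by the CD31-stained area. Per animal, section ratios are
#' averaged per region and then the infarct and penumbra ratios are divided
#' by the healthy-region ratio, so healthy maps to 1. Regions with zero
#' CD31 area are flagged and excluded from the averages.
#'
#' @param quant either one [quantify_rois()] result (a single section) or a
#'   data frame with columns `animal`, `section`, `region`,
#'   `cd31_area_mm2`, `igg_area_mm2` covering several sections/animals.
#' @param healthy_label the label of the reference region.
#' @return Object of class `extravasation_result`: `per_section` ratios and
#'   `per_animal` region means with `normalized_ratio` (healthy = 1).
#' @export
extravasation_ratio <- function(quant, healthy_label = "healthy") {
  if (inherits(quant, "area_quant")) {
    quant <- cbind(animal = "a1", section = 1L, quant$per_region)
  }
  needed <- c("animal", "section", "region", "cd31_area_mm2", "igg_area_mm2")
  stopifnot(is.data.frame(quant), all(needed %in% names(quant)))
  per_section <- quant
  per_section$flagged <- per_section$cd31_area_mm2 <= 0
  if (any(per_section$flagged)) {
    warnf("%d section-region entries have zero CD31 area; flagged and excluded",
          sum(per_section$flagged))
  }
  per_section$ratio <- ifelse(per_section$flagged, NA_real_,
                              per_section$igg_area_mm2 /
                                per_section$cd31_area_mm2)
  keep <- per_section[!per_section$flagged, ]
  per_animal <- do.call(rbind, lapply(split(keep, keep$animal), function(a) {
    means <- tapply(a$ratio, a$region, mean)
    healthy <- means[[healthy_label]]
    if (is.null(healthy) || is.na(healthy)) {
      stopf("animal '%s' has no usable '%s' region to normalize to",
            a$animal[1], healthy_label)
    }
    data.frame(animal = a$animal[1], region = names(means),
               ratio = as.numeric(means),
               normalized_ratio = as.numeric(means) / healthy)
  }))
  rownames(per_animal) <- NULL
  structure(list(per_section = per_section, per_animal = per_animal,
                 healthy_label = healthy_label),
            class = "extravasation_result")
}

#' @export
print.extravasation_result <- function(x, ...) {
  cat("<extravasation_result>\n")
  print(x$per_animal)
  invisible(x)
}

#' Mean fluorescence per ROI
#'
#' Arithmetic mean pixel intensity inside each ROI of an equal-area ROI set,
#' as measured on whole-brain fluorescence scans.
#'
#' @param image intensity matrix.
#' @param rois a [roi_set()]; all ROIs must share one area.
#' @return Data frame with `roi`, `label`, `mean_intensity`.
#' @export
roi_mean_fluorescence <- function(image, rois) {
  stopifnot(is.matrix(image), inherits(rois, "roi_set"))
  df <- rois$rois
  if (length(unique(df$height * df$width)) != 1L) {
    stopf("invariant violated: homing ROIs must all have the same area")
  }
  check_rois_within(rois, dim(image))
  data.frame(roi = seq_len(nrow(df)), label = df$label,
             mean_intensity = vapply(seq_len(nrow(df)), function(i)
               mean(roi_slice(image, df, i)), numeric(1)))
}

#' Hemisphere-normalized homing ratio
#'
#' Normalizes ischemic-hemisphere ROI fluorescence to the paired healthy-
#' hemisphere ROIs, removing label-efficiency differences between EV
#' preparations: the homing ratio is the mean of the ischemic ROI means over
#' the mean of the healthy ROI means; per-pair ratios are also returned.
#'
#' @param ischemic,healthy numeric vectors of paired ROI mean intensities
#'   (same length, matched order).
#' @return List with `ratio` and `pair_ratios`.
#' @export
normalize_hemispheres <- function(ischemic, healthy) {
  if (length(ischemic) != length(healthy) || length(ischemic) == 0L) {
    stopf("ischemic and healthy ROI means must be paired (same nonzero length)")
  }
  if (mean(healthy) == 0 || any(healthy == 0)) {
    stopf("healthy-hemisphere ROI mean of 0; cannot normalize")
  }
  list(ratio = mean(ischemic) / mean(healthy),
       pair_ratios = ischemic / healthy)
}
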