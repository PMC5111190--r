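#' Background-normalized optical density
#'
#' `(od - od_bkg) / od_bkg`: zero when a region of interest is as dark as
#' the field background, negative when staining falls below background.
#'
#' @param od mean optical density of the ROI (vectorized).
#' @param od_bkg background optical density of the field (> 0).
#' @return Normalized OD values.
#' @export
normalized_od <- function(od, od_bkg) {
  if (any(!is.finite(od_bkg)) || any(od_bkg <= 0)) {
    stop_invalid("`od_bkg` must be strictly positive",
                 "septapk_invalid_parameter")
  }
  (od - od_bkg) / od_bkg
}

#' Summarize ROI densitometry measurements per specimen
#'
#' Normalizes every ROI to its field background and reports mean, SD and
#' count per lectin x group. The sampling design calls for at least eight
#' ROIs in each of ten optical fields; thinner designs are summarized with
#' a warning.
#'
#' @param measurements data frame with columns `lectin`, `group`,
#'   `field_id`, `roi_id`, `od`, `od_bkg`.
#' @return Data frame of class `specimen_summary` with columns `lectin`,
#'   `group`, `mean`, `sd`, `n_roi`, `n_fields`.
#' @export
summarize_od <- function(measurements) {
  need <- c("lectin", "group", "field_id", "roi_id", "od", "od_bkg")
  if (nrow(measurements) == 0L) {
    stop_invalid("no ROI measurements supplied", "septapk_invalid_data")
  }
  if (!all(need %in% names(measurements))) {
    stop_invalid(paste("OD table must contain columns:",
                       paste(need, collapse = ", ")),
                 "septapk_invalid_data")
  }
  m <- measurements
  m$norm <- normalized_od(m$od, m$od_bkg)
  key <- interaction(m$lectin, m$group, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    i <- key == k
    fields <- unique(m$field_id[i])
    per_field <- vapply(fields, function(f) sum(i & m$field_id == f),
                        numeric(1))
    if (length(fields) < 10 || any(per_field < 8)) {
      warning(sprintf(
        "%s: sampling below the 8 ROIs x 10 fields design (%d fields, min %d ROIs/field)",
        k, length(fields), min(per_field)))
    }
    data.frame(lectin = m$lectin[i][1], group = m$group[i][1],
               mean = mean(m$norm[i]), sd = stats::sd(m$norm[i]),
               n_roi = sum(i), n_fields = length(fields))
  }))
  class(out) <- c("specimen_summary", "data.frame")
  out
}

#' Extract ROI optical densities from a grayscale field image
#'
#' Converts an 8-bit grayscale intensity matrix to optical density,
#' \eqn{OD = -\log_{10}(I / I_0)} with \eqn{I_0 = 255}, then averages OD
#' over square ROIs placed uniformly at random (seeded) away from the
#' field borders. The field background OD is the median OD of the whole
#' field. This path exists to exercise the densitometry pipeline end to
#' end on synthetic fields; it performs no segmentation.
#'
#' @param img integer/numeric matrix of intensities in `[1, 255]`.
#' @param n_roi number of ROIs to place; default 8.
#' @param roi_px ROI side length in pixels; default 5.
#' @param seed integer seed for ROI placement.
#' @return Data frame with columns `roi_id`, `od`, `od_bkg`.
#' @export
image_roi_od <- function(img, n_roi = 8, roi_px = 5, seed = 1L) {
  stopifnot(is.matrix(img), min(img) >= 1, max(img) <= 255)
  od_img <- -log10(img / 255)
  od_bkg <- stats::median(od_img)
  nr <- nrow(img); nc <- ncol(img)
  margin <- roi_px  # keep ROIs clear of the field border
  stopifnot(nr > 2 * margin + roi_px, nc > 2 * margin + roi_px)
  pos <- with_seed(seed, data.frame(
    r = sample(seq(margin + 1L, nr - margin - roi_px), n_roi, replace = TRUE),
    c = sample(seq(margin + 1L, nc - margin - roi_px), n_roi, replace = TRUE)))
  od <- vapply(seq_len(n_roi), function(i) {
    mean(od_img[pos$r[i]:(pos$r[i] + roi_px - 1L),
                pos$c[i]:(pos$c[i] + roi_px - 1L)])
  }, numeric(1))
  data.frame(roi_id = seq_len(n_roi), od = od, od_bkg = od_bkg)
}

#' Render a synthetic stained-field image
#'
#' Builds a grayscale field whose stained patches sit at a prescribed
#' optical density above a uniform background, for exercising
#' [image_roi_od()]. Labelled synthetic: it imitates only the intensity
#' statistics of a stained section, not its morphology.
#'
#' @param od_signal target OD of stained pixels.
#' @param od_bkg background OD.
#' @param size image side, pixels.
#' @param frac_stained fraction of pixels stained.
#' @param seed integer seed.
#' @return An intensity matrix in `[1, 255]`.
#' @export
synthetic_field_image <- function(od_signal = 0.4, od_bkg = 0.2,
                                  size = 64L, frac_stained = 0.5,
                                  seed = 1L) {
  check_positive(od_bkg, "od_bkg")
  with_seed(seed, {
    stained <- matrix(stats::runif(size * size) < frac_stained, size, size)
    od <- ifelse(stained, od_signal, od_bkg)
    pmax(pmin(round(255 * 10^(-od)), 255), 1)
  })
}
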