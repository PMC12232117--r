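#' Construct an ROI timelapse trace
#'
#' An in vitro trace of ROI mean gray values per frame, with the frame at
#' which the ligand was added. Ten pre-ligand frames are required to form
#' the F0 baseline.
#'
#' @param frames Numeric vector of mean gray values, all >= 0.
#' @param ligand_frame 1-based frame index of ligand addition, >= 11.
#' @return An `roi_trace`.
#' @export
roi_trace <- function(frames, ligand_frame) {
  frames <- as.numeric(frames)
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("frame values must be finite and >= 0", call. = FALSE)
  if (ligand_frame < 11)
    stop("ligand_frame must be >= 11 (10 baseline frames needed)",
         call. = FALSE)
  if (ligand_frame > length(frames))
    stop("ligand_frame beyond end of trace", call. = FALSE)
  structure(list(frames = frames, ligand_frame = as.integer(ligand_frame)),
            class = "roi_trace")
}

#' Fractional fluorescence response of an ROI
#'
#' dF/F0 per frame, `(F(t) - F0) / F0`, with F0 the mean of the 10 frames
#' immediately before ligand addition; the peak response is the maximum
#' dF/F0 from the ligand frame onward.
#'
#' @param trace An [roi_trace()].
#' @return A list: `dff` (per-frame series) and `peak_dff`.
#' @export
dff_response <- function(trace) {
  stopifnot(inherits(trace, "roi_trace"))
  lf <- trace$ligand_frame
  f0 <- mean(trace$frames[(lf - 10):(lf - 1)])
  if (f0 <= 0)
    stop("degenerate baseline: F0 must be positive", call. = FALSE)
  dff <- (trace$frames - f0) / f0
  list(dff = dff, peak_dff = max(dff[lf:length(dff)]))
}

#' Basal brightness from the brightest pixels
#'
#' Mean of the top `top_fraction` of pixel values (the thresholded plasma
#' membranes of expressing cells). The cutoff is the
#' `ceiling(top_fraction * n)`-th brightest value; ties at the cutoff are
#' all included.
#'
#' @param image_values Numeric vector of pixel values, length >= 10.
#' @param top_fraction Fraction of brightest pixels to average
#'   (default 0.10).
#' @return Mean brightness of the selected pixels.
#' @export
basal_brightness <- function(image_values, top_fraction = 0.10) {
  image_values <- as.numeric(image_values)
  n <- length(image_values)
  if (n == 0) stop("empty pixel input", call. = FALSE)
  if (n < 10) stop("need at least 10 pixels", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  m <- ceiling(top_fraction * n)
  cutoff <- sort(image_values, decreasing = TRUE)[m]
  mean(image_values[image_values >= cutoff])
}
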