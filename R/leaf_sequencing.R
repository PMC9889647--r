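# Convert predicted aperture channels into deliverable MLC control points
# and MU weights, and splice them into a template plan.

#' Suppress low-intensity noise in a predicted channel
#'
#' Zeros every pixel below `threshold_fraction` of the channel maximum.
#' @param channel Non-negative 2D array.
#' @param threshold_fraction Fraction of the channel maximum (default 0.02,
#'   i.e. a 2 percent intensity threshold).
#' @return The thresholded channel.
#' @export
threshold_channel <- function(channel, threshold_fraction = 0.02) {
  if (any(channel < 0)) stop("channel has negative values")
  mx <- max(channel)
  channel[channel < threshold_fraction * mx] <- 0
  channel
}

#' Assign the segment MU from the channel maximum and binarize
#'
#' The MU weight is the maximum intensity of the (thresholded) channel,
#' de-normalized by `mu_scale`; every surviving pixel is forced to that
#' maximum.
#' @param channel A thresholded channel.
#' @param mu_scale MU normalization constant (1 leaves the value normalized).
#' @return List with `mu`, the forced `channel`, and `empty` (TRUE when the
#'   channel had no signal).
#' @export
assign_mu <- function(channel, mu_scale = 1) {
  mx <- max(channel)
  if (mx <= 0) return(list(mu = 0, channel = channel, empty = TRUE))
  channel[channel > 0] <- mx
  list(mu = mx * mu_scale, channel = channel, empty = FALSE)
}

#' Convert a binarized aperture channel to MLC leaf and diaphragm positions
#'
#' The channel's row axis (linac X) is resampled to the machine's leaf rows;
#' within each row the open interval spans from the first to the last open
#' pixel (interior holes are bridged, since one leaf pair cannot form two
#' openings). Closed rows park both leaves at the field edge. Diaphragms are
#' set to the bounding box of the open rows along X. Positions are quantized
#' to 0.1 mm.
#'
#' @param channel A binarized `size x size` channel.
#' @param machine A [machine_model()].
#' @param extent_x,extent_y Physical extents of the channel raster (mm at
#'   isocenter); default the full machine field.
#' @return A control point: `intervals` (`n_leaf_rows x 2`, NA rows closed),
#'   `diaphragm` (length 2, mm along X), or NULL when nothing remains open.
#' @export
segment_to_leaves <- function(channel, machine, extent_x = NULL,
                              extent_y = NULL) {
  if (is.null(extent_x)) extent_x <- c(-1, 1) * machine$field_x_extent / 2
  if (is.null(extent_y)) extent_y <- c(-1, 1) * machine$field_y_extent / 2
  nr <- nrow(channel); nc <- ncol(channel)
  xs <- extent_x[1] + (seq_len(nr) - 0.5) * diff(extent_x) / nr
  ys <- extent_y[1] + (seq_len(nc) - 0.5) * diff(extent_y) / nc
  rows <- leaf_row_of(xs, machine)
  fy2 <- machine$field_y_extent / 2
  py <- diff(extent_y) / nc
  intervals <- matrix(NA_real_, machine$n_leaf_rows, 2)
  for (r in unique(rows[!is.na(rows)])) {
    sub <- channel[which(rows == r), , drop = FALSE]
    open_cols <- which(colSums(sub) > 0)
    if (length(open_cols) == 0) next
    lo <- max(ys[min(open_cols)] - py / 2, -fy2)
    up <- min(ys[max(open_cols)] + py / 2, fy2)
    intervals[r, ] <- round(c(lo, up), 1)
  }
  open_rows <- which(!is.na(intervals[, 1]))
  if (length(open_rows) == 0) return(NULL)
  bounds <- leaf_row_bounds(range(open_rows), machine)
  list(intervals = intervals,
       diaphragm = round(c(bounds[1, "lower"], bounds[2, "upper"]), 1),
       parked = -fy2)
}

#' Sequence a predicted aperture stack into deliverable segments
#'
#' Applies the intensity threshold, assigns MU from the channel maximum,
#' and converts each surviving channel to MLC positions, preserving delivery
#' order. Channels that are empty after thresholding are dropped.
#'
#' @param stack An `aperture_stack` (predicted or ground truth).
#' @param machine A [machine_model()].
#' @param mu_scale MU de-normalization constant; defaults to the stack's own.
#' @param threshold_fraction Intensity threshold (fraction of channel max).
#' @return List of `mlc_segment`s with `diaphragm` attributes (possibly
#'   empty).
#' @export
sequence_stack <- function(stack, machine, mu_scale = NULL,
                           threshold_fraction = 0.02) {
  if (is.null(mu_scale)) mu_scale <- stack$mu_scale
  if (is.null(mu_scale) || is.na(mu_scale)) mu_scale <- 1
  segs <- list()
  for (c in seq_len(dim(stack$channels)[3])) {
    ch <- threshold_channel(stack$channels[, , c], threshold_fraction)
    am <- assign_mu(ch, mu_scale)
    if (am$empty) next
    cp <- segment_to_leaves(am$channel, machine, stack$extent_x,
                            stack$extent_y)
    if (is.null(cp)) next
    seg <- new_segment(cp$intervals, am$mu)
    seg$diaphragm <- cp$diaphragm
    segs[[length(segs) + 1]] <- seg
  }
  segs
}

#' Sequence predicted stacks for every beam and splice into a template plan
#'
#' Rebuilds a deliverable plan from predicted aperture stacks: the template's
#' beam angles, isocenter and metadata are preserved verbatim; only segments
#' (MLC positions and MU weights) are replaced.
#'
#' @param stacks List of `aperture_stack`s, one per template beam.
#' @param template_plan The prior plan being replanned.
#' @param machine A [machine_model()].
#' @param threshold_fraction Intensity threshold.
#' @param on_empty_beam `"error"` (default: a replan must not silently lose a
#'   beam) or `"keep"` (keep the beam with zero segments, for diagnostic
#'   comparisons of deliberately bad models).
#' @return A new `plan`.
#' @export
sequence_plan <- function(stacks, template_plan, machine,
                          threshold_fraction = 0.02,
                          on_empty_beam = c("error", "keep")) {
  on_empty_beam <- match.arg(on_empty_beam)
  if (length(stacks) != length(template_plan$beams)) {
    stop(sprintf("%d stacks for %d template beams", length(stacks),
                 length(template_plan$beams)))
  }
  plan <- template_plan
  for (b in seq_along(stacks)) {
    segs <- sequence_stack(stacks[[b]], machine,
                           threshold_fraction = threshold_fraction)
    if (length(segs) == 0 && on_empty_beam == "error") {
      stop(sprintf("beam %d has no surviving segments after thresholding", b))
    }
    plan$beams[[b]]$segments <- segs
  }
  plan$replanned <- TRUE
  plan
}
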