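#' Linac machine geometry
#'
#' Describes the beam-shaping geometry of an MR-Linac-like machine: a bank of
#' MLC leaves stacked along the linac X-axis, with leaf travel along the linac
#' Y-axis and diaphragm (jaw) travel along X. All lengths are mm projected at
#' isocenter.
#'
#' @param leaf_width Projected leaf width at isocenter (mm).
#' @param field_x_extent Maximum field extent along the linac X-axis, the
#'   leaf-stacking / diaphragm-travel axis (mm).
#' @param field_y_extent Maximum field extent along the linac Y-axis, the
#'   leaf-travel axis (mm).
#' @return An object of class `machine_model` with derived `n_leaf_rows`.
#' @examples
#' m <- machine_model()
#' m$n_leaf_rows  # 80
#' @export
machine_model <- function(leaf_width = 7.15, field_x_extent = 572,
                          field_y_extent = 220) {
  n_rows <- field_x_extent / leaf_width
  if (abs(n_rows - round(n_rows)) > 1e-9) {
    stop("field_x_extent must be an integer multiple of leaf_width")
  }
  structure(list(
    leaf_width = leaf_width,
    field_x_extent = field_x_extent,
    field_y_extent = field_y_extent,
    n_leaf_rows = as.integer(round(n_rows)),
    leaf_travel_axis = "Y",
    diaphragm_axis = "X"
  ), class = "machine_model")
}

#' @export
print.machine_model <- function(x, ...) {
  cat(sprintf(
    "<machine_model> %d leaf rows x %.2f mm (X extent %.1f mm, Y extent %.1f mm)\n",
    x$n_leaf_rows, x$leaf_width, x$field_x_extent, x$field_y_extent))
  invisible(x)
}

# leaf-row index (1-based) containing linac-X position x_mm; NA outside field
leaf_row_of <- function(x_mm, machine) {
  r <- floor((x_mm + machine$field_x_extent / 2) / machine$leaf_width) + 1
  r[x_mm < -machine$field_x_extent / 2 | x_mm >= machine$field_x_extent / 2] <- NA
  r[r > machine$n_leaf_rows] <- machine$n_leaf_rows
  as.integer(r)
}

# linac-X boundaries [lower, upper) of a 1-based leaf row
leaf_row_bounds <- function(row, machine) {
  lo <- -machine$field_x_extent / 2 + (row - 1) * machine$leaf_width
  cbind(lower = lo, upper = lo + machine$leaf_width)
}
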