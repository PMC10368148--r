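#' Build a rectangular MEA electrode layout
#'
#' Constructs the electrode-layout table for a planar multielectrode array:
#' a `rows x cols` grid at a fixed pitch, with hippocampal region labels
#' assigned by column (columns left of `region_split` are CA3, the rest CA1,
#' emulating a slice draped across the array with CA3 on one side and CA1 on
#' the other) and a single internal reference electrode that is excluded
#' from all downstream analyses.
#'
#' @param rows,cols grid dimensions; `rows * cols` must equal 60 (the
#'   commercial 60-channel pMEA geometry).
#' @param pitch_um interelectrode distance in micrometers (default 100).
#' @param region_split column index in `0..cols`; columns `< region_split`
#'   are labeled CA3, columns `>= region_split` CA1. Use 0 to label all
#'   recording electrodes CA1 (degenerate split).
#' @param reference_id electrode id (0-based) flagged as the internal
#'   reference; it receives region label `"none"`.
#'
#' @return A data.frame of class `gbo_layout` with columns `electrode_id`
#'   (0..59), `row`, `col`, `x_um`, `y_um`, `region` (`CA1`, `CA3`, `none`)
#'   and `is_reference`.
#' @examples
#' lay <- make_layout()
#' table(lay$region)
#' @export
make_layout <- function(rows = 6, cols = 10, pitch_um = 100,
                        region_split = 5, reference_id = 14) {
  if (rows * cols != 60)
    .gbo_error(sprintf("rows * cols must be 60, got %d", rows * cols),
               "gbo_config_error")
  if (region_split < 0 || region_split > cols)
    .gbo_error("region_split must lie in 0..cols", "gbo_config_error")
  if (reference_id < 0 || reference_id >= 60)
    .gbo_error("reference_id must lie in 0..59", "gbo_config_error")
  id <- 0:59
  col <- id %% cols
  row <- id %/% cols
  region <- ifelse(col < region_split, "CA3", "CA1")
  is_ref <- id == reference_id
  region[is_ref] <- "none"
  out <- data.frame(
    electrode_id = id, row = row, col = col,
    x_um = col * pitch_um, y_um = row * pitch_um,
    region = factor(region, levels = c("CA1", "CA3", "none")),
    is_reference = is_ref)
  class(out) <- c("gbo_layout", "data.frame")
  out
}

validate_layout <- function(layout) {
  stopifnot(is.data.frame(layout))
  need <- c("electrode_id", "row", "col", "x_um", "y_um", "region",
            "is_reference")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    .gbo_error(paste("layout missing column(s):",
                     paste(miss, collapse = ", ")), "gbo_format_error")
  if (nrow(layout) != 60)
    .gbo_error("layout must have exactly 60 electrodes", "gbo_config_error")
  if (sum(layout$is_reference) != 1)
    .gbo_error("layout must flag exactly one reference electrode",
               "gbo_config_error")
  invisible(layout)
}

#' Non-reference electrodes of a layout
#' @param layout a `gbo_layout`
#' @param regions optional subset of region labels to keep
#' @return integer electrode ids
#' @export
recording_electrodes <- function(layout, regions = c("CA1", "CA3")) {
  keep <- !layout$is_reference & layout$region %in% regions
  layout$electrode_id[keep]
}
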