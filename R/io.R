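#' Write / read a recording as an HDF5 container
#'
#' The container stores `/data` (channels x samples, microvolts), `/layout`
#' and `/epochs` as tables, scalar metadata (`/fs_hz`, `/slice_id`) and the
#' simulation ground truth, when present, as a JSON string under
#' `/ground_truth`. The round trip is lossless.
#'
#' @param rec a `gbo_recording` (or `gbo_lfp`)
#' @param path file path (overwritten if it exists)
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(rec$data, path, "data")
  lay <- as.data.frame(rec$layout)
  lay$region <- as.character(lay$region)
  lay$is_reference <- as.integer(lay$is_reference)  # HDF5 has no logical
  rhdf5::h5write(lay, path, "layout")
  rhdf5::h5write(rec$epochs, path, "epochs")
  rhdf5::h5write(rec$fs_hz, path, "fs_hz")
  rhdf5::h5write(rec$slice_id, path, "slice_id")
  if (!is.null(rec$ground_truth))
    rhdf5::h5write(as.character(jsonlite::toJSON(
      unclass(rec$ground_truth), auto_unbox = TRUE, digits = NA)),
      path, "ground_truth")
  if (!is.null(rec$provenance))
    rhdf5::h5write(as.character(jsonlite::toJSON(
      rec$provenance, auto_unbox = TRUE, digits = NA)), path, "provenance")
  invisible(path)
}

#' @rdname write_recording
#' @param path file path of an existing container
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    .gbo_error(sprintf("no such file: %s", path), "gbo_format_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  have <- rhdf5::h5ls(path)$name
  for (comp in c("data", "layout", "epochs", "fs_hz", "slice_id")) {
    if (!comp %in% have)
      .gbo_error(sprintf("malformed container: missing component '%s'", comp),
                 "gbo_format_error")
  }
  undim <- function(df) {         # rhdf5 returns 1-d arrays for columns
    df[] <- lapply(df, as.vector)
    df
  }
  data <- rhdf5::h5read(path, "data")
  lay <- undim(rhdf5::h5read(path, "layout"))
  lay$region <- factor(lay$region, levels = c("CA1", "CA3", "none"))
  lay$is_reference <- as.logical(lay$is_reference)
  class(lay) <- c("gbo_layout", "data.frame")
  epochs <- undim(rhdf5::h5read(path, "epochs"))
  gt <- NULL
  if ("ground_truth" %in% have) {
    gt <- jsonlite::fromJSON(rhdf5::h5read(path, "ground_truth"))
    gt$duration_s <- unlist(gt$duration_s)
    class(gt) <- "gbo_sim_config"
  }
  prov <- if ("provenance" %in% have)
    jsonlite::fromJSON(rhdf5::h5read(path, "provenance")) else NULL
  fs <- as.numeric(rhdf5::h5read(path, "fs_hz"))
  rec <- new_recording(data, fs, lay, epochs,
                       as.character(rhdf5::h5read(path, "slice_id")),
                       ground_truth = gt, provenance = prov)
  if (!is.null(prov)) class(rec) <- c("gbo_lfp", class(rec))
  rec
}
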