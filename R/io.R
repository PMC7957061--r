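#' Write a label volume as multipage TIFF plus JSON sidecar
#'
#' One 8-bit grayscale page per z slice; pitch, label map and origin go into
#' `<path>.json`. Label ids must lie in 0..255.
#'
#' @param vol a [label_volume()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_label_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "calf_volume"))
  if (max(vol$labels) > 255L || min(vol$labels) < 0L) {
    abort("TIFF export supports label ids 0..255 only.")
  }
  d <- dim(vol$labels)
  pages <- lapply(seq_len(d[3]), function(k) {
    # tiff stores matrices as rows x cols displayed images; keep (x, y) as-is
    vol$labels[, , k] / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(pitch_nm = vol$pitch_nm,
               label_map = as.list(vol$label_map),
               origin_nm = vol$origin_nm,
               dim = d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label volume written by [write_label_volume_tiff()]
#'
#' @param path TIFF path; `<path>.json` must exist.
#' @return a [label_volume()].
#' @export
read_label_volume_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    abort(sprintf("Metadata sidecar `%s` not found.", side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  labels <- array(0L, d)
  for (k in seq_len(d[3])) {
    labels[, , k] <- as.integer(round(pages[[k]] * 255))
  }
  label_volume(labels,
               pitch_nm = as.double(meta$pitch_nm),
               label_map = setNames(as.integer(unlist(meta$label_map)),
                                    names(meta$label_map)),
               origin_nm = as.double(meta$origin_nm))
}

#' Write a per-synapse morphometrics table as CSV
#'
#' @param morph tibble with at least `synapse_id`, `svr_um_inv`,
#'   `coverage_pre`, `coverage_post`, `ecs_fraction`, `astro_fraction`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphometrics_csv <- function(morph, path) {
  need <- c("synapse_id", "svr_um_inv", "coverage_pre", "coverage_post",
            "ecs_fraction", "astro_fraction")
  miss <- setdiff(need, names(morph))
  if (length(miss)) {
    abort(paste0("Missing morphometrics columns: ", paste(miss, collapse = ", ")))
  }
  readr::write_csv(dplyr::select(morph, dplyr::all_of(need),
                                 dplyr::any_of(c("area_um2", "volume_um3"))),
                   path)
  invisible(path)
}

#' Adapter interface for externally segmented EM volumes
#'
#' Documented stub: native segmentation-tool exports (e.g. VAST Lite exports
#' of the Kasthuri saturated reconstruction) are out of scope here. To use
#' such data, convert each 1.2 um sample to a multipage TIFF + JSON sidecar
#' with the layout produced by [write_label_volume_tiff()] (dataset of
#' compartment ids, `pitch_nm`, `label_map`, `origin_nm`) and load it with
#' [read_label_volume_tiff()].
#'
#' @param path path to a native export.
#' @return never returns; raises an informative error.
#' @export
read_vast_export <- function(path) {
  abort(paste0(
    "Native segmentation exports are not parsed by this package. ",
    "Convert the volume to multipage TIFF + JSON sidecar ",
    "(see ?read_label_volume_tiff) and load that instead."))
}
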