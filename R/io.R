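#' Write a fluorescence image as 16-bit TIFF with a ground-truth sidecar
#'
#' Intensities are stored as 16-bit samples (clamped to 0..65535); when the
#' image carries simulation metadata, a JSON sidecar (`<path>.json`) records
#' the rendering calibration and ground-truth particle list.
#'
#' @param img a [fluorescence_image()].
#' @param path output TIFF path.
#' @param sidecar write the JSON ground-truth sidecar when metadata exists.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path, sidecar = TRUE) {
  px <- as_pixels(img)
  tiff::writeTIFF(pmin(pmax(px, 0), 65535) / 65535, path,
                  bits.per.sample = 16L)
  if (sidecar && inherits(img, "fluorescence_image") && length(img$meta)) {
    meta <- img$meta
    if (!is.null(meta$ground_truth)) {
      gt <- meta$ground_truth
      meta$ground_truth <- list(particles = gt$particles, dim = gt$dim,
                                n_t = gt$n_t, c_t = gt$c_t)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a 16-bit TIFF as a fluorescence image
#'
#' @param path TIFF path.
#' @param pixel_size micrometres per pixel.
#' @return A [fluorescence_image()] with intensities on the 0..65535 scale.
#' @export
read_image_tiff <- function(path, pixel_size = 0.1) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  fluorescence_image(px * 65535, pixel_size = pixel_size)
}

#' Write / read tidy I-V data as CSV
#'
#' Columns: `cell_id`, `group`, `voltage_mV`, `current_pApF`.
#'
#' @param dataset an `iv_dataset` data.frame.
#' @param path CSV path.
#' @return `path` / the data.frame.
#' @export
write_iv_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_id", "group", "voltage_mV", "current_pApF") %in%
                  names(out)))
  class(out) <- c("iv_dataset", "data.frame")
  out
}

#' Write / read sequence records as FASTA
#'
#' @param seqs list of [sequence_record()]s.
#' @param path FASTA path.
#' @return `path` / a list of [sequence_record()]s.
#' @export
write_fasta_records <- function(seqs, path) {
  if (inherits(seqs, "sequence_record")) seqs <- list(seqs)
  seqinr::write.fasta(lapply(seqs, function(s) seq_chars(s$seq)),
                      names = vapply(seqs, `[[`, character(1), "id"),
                      file.out = path)
  invisible(path)
}

#' @rdname write_fasta_records
#' @export
read_fasta_records <- function(path) {
  raw <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  lapply(names(raw), function(nm) sequence_record(nm, toupper(raw[[nm]][1])))
}

#' Write / read gradient profiles as CSV
#'
#' Columns: `fraction` (1..15, top to bottom), `signal`.
#'
#' @param profile a [gradient_profile()].
#' @param path CSV path.
#' @param raft_fractions raft indices used when reading.
#' @return `path` / a [gradient_profile()].
#' @export
write_gradient_csv <- function(profile, path) {
  utils::write.csv(data.frame(fraction = 1:15, signal = profile$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gradient_csv
#' @export
read_gradient_csv <- function(path, raft_fractions = 3:6) {
  d <- utils::read.csv(path)
  stopifnot(all(c("fraction", "signal") %in% names(d)))
  gradient_profile(d$signal[order(d$fraction)], raft_fractions)
}
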