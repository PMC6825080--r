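# Disk representation of a cohort: 8-bit PNG images, 0/255 PNG masks and a
# CSV manifest (image_id, patient_id, class, reader_id, paths).

#' Write a cohort to a directory of PNGs plus a CSV manifest
#'
#' @param samples list of [roi_sample()] objects.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data frame.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    img_path <- file.path(dir, paste0(s$image_id, ".png"))
    mask_path <- file.path(dir, paste0(s$image_id, "_mask.png"))
    png::writePNG(s$image / 255, img_path)
    png::writePNG(s$mask * 1.0, mask_path)
    data.frame(image_id = s$image_id, patient_id = s$patient_id,
               class = s$class_label,
               reader_id = if (is.null(s$reader_id)) NA_character_ else s$reader_id,
               image_path = basename(img_path), mask_path = basename(mask_path),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the PNGs.
#' @return list of [roi_sample()] objects.
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- round(png::readPNG(file.path(dir, row$image_path)) * 255)
    mask <- png::readPNG(file.path(dir, row$mask_path)) > 0.5
    roi_sample(img, mask, row$class, row$patient_id, row$image_id,
               reader_id = if (is.na(row$reader_id)) NULL else row$reader_id)
  })
}
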