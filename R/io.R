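#' Write a clip as a PNG frame directory
#'
#' Frames are written as `frame_0001.png`, ... in acquisition order,
#' together with a small `clip.json` carrying the labels and, for
#' synthetic clips, the ray geometry.
#'
#' @param clip a [LUSClip-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeClip <- function(clip, dir) {
  stopifnot(is(clip, "LUSClip"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nFrames(clip)
  for (i in seq_len(n))
    png::writePNG(clip@frames[, , i],
                  file.path(dir, sprintf("frame_%04d.png", i)))
  meta <- list(clip_id = clip@clipId, patient_id = clip@patientId,
               clip_label = clip@clipLabel, severity = clip@severity,
               homogeneity = clip@homogeneity,
               frame_labels = clip@frameLabels,
               ray_angles = clip@rayAngles,
               ray_width_angle = clip@rayWidthAngle,
               sector = clip@sector)
  jsonlite::write_json(meta, file.path(dir, "clip.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a clip from a PNG frame directory
#'
#' @param dir directory written by [writeClip()].
#' @return A [LUSClip-class].
#' @export
readClip <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "clip.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frames found in ", dir)
  first <- png::readPNG(files[1])
  arr <- array(0, c(dim(first)[1], dim(first)[2], length(files)))
  for (i in seq_along(files)) {
    px <- png::readPNG(files[i])
    if (length(dim(px)) == 3L) px <- px[, , 1]
    arr[, , i] <- px
  }
  new("LUSClip", frames = arr,
      frameLabels = as.character(meta$frame_labels),
      clipId = meta$clip_id, patientId = meta$patient_id,
      clipLabel = meta$clip_label, severity = meta$severity,
      homogeneity = meta$homogeneity,
      rayAngles = as.numeric(meta$ray_angles %||% numeric()),
      rayWidthAngle = as.numeric(meta$ray_width_angle %||% 0),
      sector = lapply(meta$sector, as.numeric))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort manifest
#'
#' @param manifest manifest data.frame (see [generateCohort()]).
#' @param path CSV output path.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path CSV written by [writeManifest()].
#' @return data.frame.
#' @export
readManifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
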