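# Image and table I/O. Images are numeric matrices of counts or photons;
# TIFF reading preserves the stored sample values (no rescaling to [0, 1]).

#' Read a grayscale image
#'
#' Reads a single-frame or multi-frame grayscale TIFF (or a PNG, for masks).
#' Integer TIFF samples are returned as stored (counts), floating-point
#' samples as-is; multi-channel images are reduced to their first channel.
#'
#' @param path file path.
#' @param all if `TRUE`, return a list of frames; otherwise the first frame.
#' @return Numeric matrix, or list of matrices when `all = TRUE`.
#' @export
read_image <- function(path, all = FALSE) {
  if (!file.exists(path)) stop_io(sprintf("cannot read image: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    frames <- list(drop_channels(img))
  } else {
    frames <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                       error = function(e) stop_io(sprintf("cannot read TIFF %s: %s",
                                                           path, conditionMessage(e))))
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, drop_channels)
  }
  if (all) frames else frames[[1]]
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale count image as 16-bit TIFF
#'
#' Pixel values are rounded to integer counts and clipped to the 16-bit
#' unsigned range; reading the file back with [read_image()] recovers the
#' counts.
#'
#' @param image numeric matrix (counts or photons).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  scaled <- pmin(pmax(round(image), 0), 65535) / 65535
  ok <- tryCatch({
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L, reduce = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write TIFF: %s", path))
  invisible(path)
}

#' Read a binary cell mask
#'
#' TIFF or PNG; any nonzero pixel is inside a cell.
#'
#' @param path file path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  read_image(path) > 0
}

detections_columns <- c("frame", "label", "row", "col", "area", "flatness",
                        "integrated_gradient", "sum_intensity",
                        "local_background", "passed_filter")

#' Write detections to CSV
#'
#' Fixed header `frame,label,row,col,area,flatness,integrated_gradient,`
#' `sum_intensity,local_background,passed_filter`, one row per candidate,
#' floating values at 6 significant digits.
#'
#' @param detections a `rasp_detections` frame.
#' @param path destination path.
#' @param frame frame index recorded in the `frame` column.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path, frame = 1L) {
  df <- data.frame(frame = frame, label = detections$label,
                   row = detections$peak_row, col = detections$peak_col,
                   area = detections$area,
                   flatness = signif(detections$flatness, 6),
                   integrated_gradient = signif(detections$integrated_gradient, 6),
                   sum_intensity = signif(detections$sum_intensity, 6),
                   local_background = signif(detections$local_background, 6),
                   passed_filter = detections$passed_filter)
  names(df) <- detections_columns
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detections written by [write_detections_csv()]
#' @param path CSV path.
#' @return Data frame with the fixed detection columns.
#' @export
read_detections_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read detections: %s", path))
  df <- utils::read.csv(path)
  missing <- setdiff(detections_columns, names(df))
  if (length(missing) > 0L)
    stop_validation(sprintf("detections CSV missing column(s): %s",
                            paste(missing, collapse = ", ")))
  df
}

#' Save a synthetic scene to disk
#'
#' Writes `<name>.tif` (the composed image), `<name>_truth.csv` (the
#' ground-truth punctum table) and `<name>_manifest.json` (seed and scene
#' bookkeeping) into `dir`.
#'
#' @param scene a `rasp_scene`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  if (!inherits(scene, "rasp_scene")) stop_validation("`scene` must be a rasp_scene")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".tif"))
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  man_path <- file.path(dir, paste0(name, "_manifest.json"))
  write_image(scene$image, img_path)
  truth <- scene$truth
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(name = name, shape = dim(scene$image), n_truth = nrow(truth),
         n_deleted = scene$n_deleted, rng_seed = scene$rng_seed,
         mean_cnr_true = mean(truth$cnr_true, na.rm = TRUE)),
    man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, truth = truth_path, manifest = man_path))
}
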