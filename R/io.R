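#' Preprocess an image file to disk
#'
#' Reads a raster, runs [preprocess_image()], and writes the cropped
#' black-background PNG plus a JSON sidecar recording the source path, crop
#' box, Otsu threshold and foreground mask area.
#'
#' @param path input JPEG/PNG/TIFF.
#' @param out_dir output directory (created if needed).
#' @param cfg a [berry_config()].
#' @return path of the written PNG, invisibly.
#' @export
preprocess_file <- function(path, out_dir, cfg = berry_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pp <- preprocess_image(read_rgb(path), cfg)
  stem <- sub("\\.[^.]+$", "", basename(path))
  out <- file.path(out_dir, paste0(stem, ".png"))
  write_rgb(pp$img, out)
  side <- list(source = path, crop_box = pp$box,
               otsu_threshold = pp$otsu_k, mask_area = sum(pp$mask))
  jsonlite::write_json(side, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report` from [repeated_eval()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    mean_accuracy = report$mean_accuracy,
    per_repeat_accuracy = report$per_repeat_accuracy,
    confusion = list(classes = colnames(report$confusion),
                     counts = unname(apply(report$confusion, 1, as.list))),
    per_sample = report$per_sample,
    settings = report$settings)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
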