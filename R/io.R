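# File I/O: gaze-set manifests (JSON), grayscale images (TIFF/PNG),
# ellipse ROI tables (CSV).

#' Read a single grayscale image as a numeric matrix
#'
#' TIFF samples are returned at their stored integer values; PNG samples are
#' returned on the 0-255 scale. Multi-channel images are converted to
#' grayscale by averaging the channels. No rescaling beyond that is applied.
#'
#' @param path image path (`.tif`/`.tiff` or `.png`).
#' @return numeric matrix, rows = y, columns = x.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path) * 255
  } else {
    stop("read_image: unsupported format '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  storage.mode(px) <- "double"
  px
}

#' Write an image, mapping defined values to the full integer range
#'
#' Defined (finite) pixels are linearly mapped to `[0, 2^bit_depth - 1]`;
#' undefined (NA) pixels are written as 0. A constant image is written at
#' mid-gray. Relative intensities survive a round trip up to quantization.
#'
#' @param image numeric matrix; NA marks undefined pixels.
#' @param path output path; `.tif`/`.tiff` or `.png` (PNG only for 8-bit).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16) {
  if (!bit_depth %in% c(8, 16)) stop("write_image: bit_depth must be 8 or 16")
  vals <- image[is.finite(image)]
  if (length(vals) == 0) stop("write_image: image has no defined pixels")
  lo <- min(vals); hi <- max(vals)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0 + 0.5
  scaled[!is.finite(scaled)] <- 0
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth)
  } else if (ext == "png") {
    if (bit_depth != 8) stop("write_image: PNG output is 8-bit only")
    png::writePNG(scaled, path)
  } else {
    stop("write_image: unsupported format '", ext, "'")
  }
  invisible(path)
}

#' Load a gaze set from a JSON manifest
#'
#' The manifest is a JSON object with optional scalars `fov_deg` (default 4)
#' and `scale_um_per_px` (default 0.77) and an array `images` of objects
#' `{path, gaze_x_deg, gaze_y_deg, id}`. Image paths are resolved relative
#' to the manifest location. Images are kept in manifest order.
#'
#' @param manifest_path path to the JSON manifest.
#' @return a [gaze_set()].
#' @export
load_gaze_set <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("load_gaze_set: manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  if (is.null(man$images) || length(man$images) < 2)
    stop("load_gaze_set: manifest must list at least 2 images")
  base <- dirname(normalizePath(manifest_path))
  images <- lapply(man$images, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    px <- read_image(p)
    gaze_image(px, c(e$gaze_x_deg, e$gaze_y_deg),
               id = if (is.null(e$id)) basename(e$path) else e$id)
  })
  gaze_set(images,
           fov_deg = if (is.null(man$fov_deg)) 4 else man$fov_deg,
           scale_um_per_px = if (is.null(man$scale_um_per_px)) 0.77
                             else man$scale_um_per_px)
}

#' Write a gaze set to image files plus a JSON manifest
#'
#' @param set a [gaze_set()].
#' @param dir output directory (created if absent).
#' @param format `"tiff"` (16-bit) or `"png"` (8-bit).
#' @return path to the written manifest, invisibly.
#' @export
write_gaze_set <- function(set, dir, format = c("tiff", "png")) {
  stopifnot(inherits(set, "gaze_set"))
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  depth <- if (format == "tiff") 16 else 8
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(set$images, function(g) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", g$id), ".", ext)
    write_image(g$pixels, file.path(dir, fn), bit_depth = depth)
    list(path = fn, gaze_x_deg = g$gaze_deg[1], gaze_y_deg = g$gaze_deg[2],
         id = g$id)
  })
  man <- list(fov_deg = set$fov_deg, scale_um_per_px = set$scale_um_per_px,
              images = entries)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

roi_header <- c("id", "modality", "cx", "cy", "a", "b", "angle_deg", "label")

#' Read an ellipse ROI table from CSV
#'
#' The CSV must have the header
#' `id,modality,cx,cy,a,b,angle_deg,label`. Rows with `a < b` are
#' normalized by swapping the axes and rotating the angle by 90 degrees
#' (a warning is raised by the underlying constructor).
#'
#' @param path CSV path.
#' @return list of [ellipse_roi()] objects (possibly empty).
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("read_rois: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = list(
    id = "character", label = "character", modality = "character"))
  if (!identical(names(df), roi_header))
    stop("read_rois: expected header ", paste(roi_header, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (!is.finite(r$a) || !is.finite(r$b))
      stop("read_rois: malformed row ", i, " in ", path)
    ellipse_roi(c(r$cx, r$cy), c(r$a, r$b), r$angle_deg,
                label = if (is.na(r$label)) "" else r$label,
                modality = r$modality, id = r$id)
  })
}

#' Write ellipse ROIs to CSV (inverse of [read_rois()])
#'
#' @param rois list of [ellipse_roi()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(id = r$id, modality = r$modality,
               cx = r$center_px[1], cy = r$center_px[2],
               a = unname(r$semi_axes_px[1]), b = unname(r$semi_axes_px[2]),
               angle_deg = r$angle_deg, label = r$label,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- stats::setNames(data.frame(matrix(nrow = 0, ncol = 8)), roi_header)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
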