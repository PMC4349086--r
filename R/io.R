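# Sequence I/O. On disk a fly is either a multi-page RGB TIFF (page 1 =
# background, pages 2..n+1 = frames; the red and blue illumination
# channels ride in the R and B planes) or a PNG directory
# (`background.png`, `frame_001.png`, ...). Pixel calibration is not
# stored in the images; it comes from the pipeline config.

frame_to_rgb <- function(frame) {
  arr <- array(0, dim = c(nrow(frame$blue), ncol(frame$blue), 3))
  arr[, , 1] <- frame$red
  arr[, , 3] <- frame$blue
  arr
}

rgb_to_frame <- function(arr) {
  if (length(dim(arr)) == 2) stop("expected an RGB image")
  list(blue = arr[, , 3], red = arr[, , 1])
}

#' Write / read a frame sequence
#'
#' `write_sequence()` stores a sequence as an 8-bit multi-page RGB TIFF
#' (page 1 is the fly-free background) or as a PNG directory;
#' `read_sequence()` restores it. Because the renderer quantizes to 8 bits,
#' a written-and-reread synthetic sequence is identical to the in-memory
#' one.
#'
#' @param seq a `frame_sequence`.
#' @param path output `.tif` file or directory (PNG mode).
#' @param format `"tiff"` or `"png"`; guessed from `path` by default.
#' @return `write_sequence()`: the path, invisibly. `read_sequence()`: a
#'   `frame_sequence` (without renderer metadata).
#' @export
write_sequence <- function(seq, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  }
  if (format == "tiff") {
    pages <- c(list(frame_to_rgb(seq$background)),
               lapply(seq$frames, frame_to_rgb))
    tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(frame_to_rgb(seq$background),
                  file.path(path, "background.png"))
    for (k in seq_along(seq$frames)) {
      png::writePNG(frame_to_rgb(seq$frames[[k]]),
                    file.path(path, sprintf("frame_%03d.png", k)))
    }
  }
  invisible(path)
}

#' @rdname write_sequence
#' @param mm_per_px pixel calibration to attach to the restored sequence.
#' @export
read_sequence <- function(path, mm_per_px = NA) {
  if (dir.exists(path)) {
    bg_file <- file.path(path, "background.png")
    if (!file.exists(bg_file)) stop("no background.png in ", path)
    frames_files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                                    full.names = TRUE))
    if (length(frames_files) == 0) stop("no frames in ", path)
    background <- rgb_to_frame(png::readPNG(bg_file))
    frames <- lapply(frames_files, function(f) rgb_to_frame(png::readPNG(f)))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) < 2) stop("TIFF must hold background + >=1 frame")
    background <- rgb_to_frame(pages[[1]])
    frames <- lapply(pages[-1], rgb_to_frame)
  }
  structure(list(frames = frames, background = background,
                 mm_per_px = mm_per_px, cfg = NULL),
            class = "frame_sequence")
}

# Discover fly sequences under a directory: fly_*.tif / fly_*.tiff files
# and fly_* subdirectories with PNG frames.
list_sequences <- function(input_dir) {
  tifs <- list.files(input_dir, pattern = "^fly_.*\\.tiff?$",
                     full.names = TRUE)
  dirs <- list.dirs(input_dir, recursive = FALSE)
  dirs <- dirs[grepl("^fly_", basename(dirs))]
  paths <- sort(c(tifs, dirs))
  ids <- sub("\\.tiff?$", "", basename(paths))
  data.frame(fly_id = ids, path = paths, stringsAsFactors = FALSE)
}
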