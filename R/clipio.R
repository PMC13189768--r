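#' Construct a frame clip
#'
#' A `frame_clip` is the basic unit of video the pipeline operates on: a
#' fixed-length stack of `D` frames with `C` channels, pixel values in
#' `[0, 1]`, a sampling rate and subject/clip identity.
#'
#' @param frames numeric array of shape `D x C x H x W`, values in `[0, 1]`.
#' @param fps frames per second (Hz), positive.
#' @param subject_id,clip_id identity strings.
#' @param t0 start-frame index of this clip in its source video (0-based).
#' @return An object of class `frame_clip`.
#' @export
frame_clip <- function(frames, fps, subject_id = "s0", clip_id = "c0", t0 = 0L) {
  stopifnot(is.numeric(frames), length(dim(frames)) == 4)
  d <- dim(frames)
  if (d[1] < 1) stop("frame_clip: D must be >= 1")
  if (!d[2] %in% c(1L, 3L)) stop("frame_clip: C must be 1 or 3")
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0)
    stop("frame_clip: fps must be a positive scalar")
  if (anyNA(frames) || any(!is.finite(frames)))
    stop("frame_clip: frames must be finite")
  if (min(frames) < 0 || max(frames) > 1)
    stop("frame_clip: pixel values must lie in [0, 1]")
  structure(
    list(frames = frames, fps = as.numeric(fps),
         subject_id = as.character(subject_id),
         clip_id = as.character(clip_id), t0 = as.integer(t0)),
    class = "frame_clip")
}

#' @export
print.frame_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_clip %s/%s: D=%d C=%d %dx%d @ %.6g fps, t0=%d>\n",
              x$subject_id, x$clip_id, d[1], d[2], d[3], d[4], x$fps, x$t0))
  invisible(x)
}

#' @export
dim.frame_clip <- function(x) dim(x$frames)

#' Construct a ground-truth blood-volume-pulse record
#'
#' @param wave numeric vector (arbitrary units), length matching the paired
#'   clip's frame count.
#' @param fps sampling rate in Hz.
#' @param hr_ref optional reference heart rate in BPM.
#' @return An object of class `bvp_record`.
#' @export
bvp_record <- function(wave, fps, hr_ref = NULL) {
  stopifnot(is.numeric(wave), length(wave) >= 1, all(is.finite(wave)),
            is.numeric(fps), fps > 0)
  structure(list(wave = as.numeric(wave), fps = as.numeric(fps),
                 hr_ref = if (is.null(hr_ref)) NULL else as.numeric(hr_ref)),
            class = "bvp_record")
}

#' Bundle clips of identical geometry into a batch
#'
#' The flattened frame axis `B = N x D` is what frame-level blocks (the stem
#' and the spatial-channel refinement module) operate over.
#'
#' @param clips list of [frame_clip()] objects sharing `D`, `C`, `H`, `W`
#'   and `fps`.
#' @return An object of class `clip_batch` with elements `clips`, `n`, `d`
#'   and `b = n * d`.
#' @export
clip_batch <- function(clips) {
  if (inherits(clips, "frame_clip")) clips <- list(clips)
  stopifnot(length(clips) >= 1)
  dims <- vapply(clips, function(cl) dim(cl$frames), integer(4))
  if (any(dims != dims[, 1]))
    stop("clip_batch: all clips must share D, C, H, W")
  fps <- vapply(clips, function(cl) cl$fps, numeric(1))
  if (any(abs(fps - fps[1]) > 1e-9))
    stop("clip_batch: all clips must share fps")
  n <- length(clips); d <- dims[1, 1]
  structure(list(clips = clips, n = n, d = d, b = n * d,
                 fps = fps[1], shape = dims[, 1]),
            class = "clip_batch")
}

#' Load frames from an array, a frame directory, or a clip fixture
#'
#' Pixel values are rescaled to `[0, 1]` by the dtype maximum (255 for 8-bit
#' style integer data, 65535 for 16-bit).  An optional rectangular region of
#' interest is cropped before rescaling; the framework assumes faces are
#' pre-cropped or covered by a fixed ROI, so no face detector is involved.
#'
#' @param source one of: a numeric array `D x C x H x W` (or `D x H x W` for
#'   single-channel), a directory containing PNG/TIFF frames (sorted by file
#'   name), or a path to an `.rds` clip fixture written by [write_clip()].
#' @param roi optional [roi_spec()] crop, applied in source-frame pixels.
#' @param fps sampling rate; required for arrays and frame directories,
#'   taken from the fixture otherwise.
#' @param subject_id,clip_id identity strings for the resulting clip.
#' @return A [frame_clip()].
#' @export
load_frames <- function(source, roi = NULL, fps = 30, subject_id = "s0",
                        clip_id = "c0") {
  if (is.character(source) && length(source) == 1) {
    if (dir.exists(source)) {
      frames <- read_frame_dir(source)
    } else if (file.exists(source)) {
      if (!grepl("\\.rds$", source, ignore.case = TRUE))
        stop("load_frames: unsupported file type (expected .rds fixture, ",
             "a frame directory, or an array)")
      clip <- read_clip(source)
      frames <- clip$frames
      fps <- clip$fps
      subject_id <- clip$subject_id
      clip_id <- clip$clip_id
    } else stop("load_frames: cannot read source '", source, "'")
  } else if (is.numeric(source)) {
    frames <- source
    if (length(dim(frames)) == 3) {
      d <- dim(frames)
      dim(frames) <- c(d[1], 1L, d[2], d[3])
    }
    if (length(dim(frames)) != 4)
      stop("load_frames: array source must be D x C x H x W")
  } else stop("load_frames: unsupported source")

  if (!is.null(roi)) frames <- crop_frames(frames, roi)
  frames <- rescale_pixels(frames)
  frame_clip(frames, fps = fps, subject_id = subject_id, clip_id = clip_id)
}

read_frame_dir <- function(path) {
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("load_frames: no PNG/TIFF frames in ", path)
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("load_frames: the 'tiff' package is needed for TIFF frames")
      tiff::readTIFF(f)
    }
  }
  imgs <- lapply(files, read_one)
  d1 <- dim(imgs[[1]])
  h <- d1[1]; w <- d1[2]
  ch <- if (length(d1) == 3) d1[3] else 1L
  if (ch == 4) ch <- 3L  # drop alpha
  frames <- array(0, dim = c(length(imgs), ch, h, w))
  for (t in seq_along(imgs)) {
    im <- imgs[[t]]
    if (length(dim(im)) == 2) dim(im) <- c(h, w, 1L)
    for (c in seq_len(ch)) frames[t, c, , ] <- im[, , c]
  }
  frames
}

rescale_pixels <- function(frames) {
  mx <- max(frames)
  if (min(frames) < 0) stop("load_frames: negative pixel values")
  if (mx > 1) {
    denom <- if (mx <= 255) 255 else 65535
    frames <- frames / denom
  }
  frames
}

#' Specify a rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the box covers source columns
#' `x0 .. x0 + width - 1` and rows `y0 .. y0 + height - 1`.
#'
#' @param x0,y0 top-left corner (0-based pixel coordinates).
#' @param width,height box size in pixels, positive.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, width, height) {
  stopifnot(width > 0, height > 0, x0 >= 0, y0 >= 0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

crop_frames <- function(frames, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  d <- dim(frames)
  h <- d[3]; w <- d[4]
  if (roi$y0 + roi$height > h || roi$x0 + roi$width > w)
    stop("roi outside frame bounds")
  frames[, , roi$y0 + seq_len(roi$height), roi$x0 + seq_len(roi$width),
         drop = FALSE]
}

#' Resize every frame of a clip
#'
#' Frames are resized independently with `EBImage`'s affine resampling
#' (bilinear by default); values are clamped back to `[0, 1]` after
#' interpolation.  Frame count, channels and sampling rate are untouched.
#'
#' @param clip a [frame_clip()].
#' @param h,w target spatial size, positive.
#' @param filter `"bilinear"` or `"nearest"`.
#' @return A resized [frame_clip()].
#' @export
resize_clip <- function(clip, h, w, filter = c("bilinear", "nearest")) {
  stopifnot(inherits(clip, "frame_clip"), h > 0, w > 0)
  filter <- match.arg(filter)
  d <- dim(clip$frames)
  if (d[3] == h && d[4] == w && filter == "nearest") return(clip)
  ebf <- if (filter == "bilinear") "bilinear" else "none"
  out <- array(0, dim = c(d[1], d[2], h, w))
  for (t in seq_len(d[1])) for (cc in seq_len(d[2])) {
    # EBImage images are x-by-y (width major); transpose in and out.
    img <- t(clip$frames[t, cc, , ])
    res <- EBImage::resize(EBImage::Image(img), w = w, h = h, filter = ebf)
    out[t, cc, , ] <- t(EBImage::imageData(res))
  }
  out <- clamp01(out)
  frame_clip(out, fps = clip$fps, subject_id = clip$subject_id,
             clip_id = clip$clip_id, t0 = clip$t0)
}

#' Segment a long frame sequence into fixed-length clips
#'
#' Windows are `[k * stride, k * stride + d)` for every `k` whose window ends
#' inside the sequence; a trailing partial window is discarded.  Each clip
#' records its start-frame index `t0`.
#'
#' @param frames numeric array `L x C x H x W` (already normalized to
#'   `[0, 1]`), or a [frame_clip()] whose frames are re-windowed.
#' @param d clip length in frames (default 160).
#' @param stride window hop in frames; defaults to `d` (non-overlapping).
#' @param fps,subject_id passed to the resulting clips.
#' @return A list of [frame_clip()] objects (possibly empty).
#' @export
segment_clips <- function(frames, d = 160L, stride = d, fps = 30,
                          subject_id = "s0") {
  if (inherits(frames, "frame_clip")) {
    fps <- frames$fps; subject_id <- frames$subject_id
    frames <- frames$frames
  }
  stopifnot(d >= 1, stride >= 1, length(dim(frames)) == 4)
  l <- dim(frames)[1]
  if (l < d) return(list())
  starts <- seq.int(0L, l - d, by = stride)
  lapply(seq_along(starts), function(k) {
    t0 <- starts[k]
    frame_clip(frames[t0 + seq_len(d), , , , drop = FALSE], fps = fps,
               subject_id = subject_id,
               clip_id = sprintf("w%03d", k - 1L), t0 = t0)
  })
}

#' Write / read a clip fixture
#'
#' The on-disk fixture is a versioned RDS list holding the frame tensor, the
#' paired BVP wave (if any), the sampling rate and identities.  The round
#' trip is bit-exact.
#'
#' @param clip a [frame_clip()].
#' @param path output file path (`.rds`).
#' @param bvp optional paired [bvp_record()].
#' @return `write_clip` returns `path` invisibly; `read_clip` returns a
#'   [frame_clip()] with, when present, the BVP attached as attribute `bvp`.
#' @export
write_clip <- function(clip, path, bvp = NULL) {
  stopifnot(inherits(clip, "frame_clip"))
  obj <- list(format = "pulseforge-clip", version = 1L,
              frames = clip$frames, fps = clip$fps,
              subject_id = clip$subject_id, clip_id = clip$clip_id,
              t0 = clip$t0,
              bvp = if (is.null(bvp)) NULL else unclass(bvp))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_clip
#' @export
read_clip <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pulseforge-clip"))
    stop("read_clip: not a pulseforge clip fixture")
  clip <- frame_clip(obj$frames, fps = obj$fps, subject_id = obj$subject_id,
                     clip_id = obj$clip_id, t0 = obj$t0)
  if (!is.null(obj$bvp))
    attr(clip, "bvp") <- bvp_record(obj$bvp$wave, obj$bvp$fps, obj$bvp$hr_ref)
  clip
}

# Internal: clip list -> (C, H, W, B) tensor with frames of clip 1 first.
batch_tensor <- function(batch) {
  stopifnot(inherits(batch, "clip_batch"))
  s <- batch$shape  # D, C, H, W
  x <- array(0, dim = c(s[2], s[3], s[4], batch$b))
  for (n in seq_len(batch$n)) {
    fr <- aperm(batch$clips[[n]]$frames, c(2, 3, 4, 1))  # C,H,W,D
    x[, , , (n - 1) * batch$d + seq_len(batch$d)] <- fr
  }
  x
}
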