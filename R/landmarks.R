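#' @keywords internal
"_PACKAGE"

# Landmark indices follow the standard 68-point facial annotation scheme,
# 0-based: jaw 0-16, brows 17-26, nose 27-35 (bridge top 27, tip 30),
# eyes 36-41 / 42-47, mouth 48-67.  All coordinates are image pixels,
# x rightward, y downward, origin top-left.  Every formula downstream uses
# distances and ratios only, so the convention is purely internal.

EYE_L_IDX <- 36:41
EYE_R_IDX <- 42:47
NOSE_BRIDGE_IDX <- 27L
NOSE_TIP_IDX <- 30L
N_LANDMARKS <- 68L

#' Look up a landmark point by its 0-based scheme index
#'
#' @param frame a `landmark_frame` (68 x 2 matrix).
#' @param i 0-based landmark index (0-67), scalar or vector.
#' @return numeric matrix with one row per requested point (columns x, y).
#' @export
landmark_pt <- function(frame, i) {
  frame[i + 1L, , drop = FALSE]
}

#' Construct a single landmark frame
#'
#' A frame is a 68 x 2 numeric matrix of pixel coordinates with a timestamp
#' (seconds) and a frame index attached as attributes.
#'
#' @param points numeric 68 x 2 matrix, or length-136 vector ordered
#'   x0, y0, ..., x67, y67.
#' @param timestamp time of the frame in seconds.
#' @param frame_index non-negative integer identifier, unique within a stream.
#' @return a `landmark_frame` object.
#' @export
landmark_frame <- function(points, timestamp = 0, frame_index = 0L) {
  if (is.null(dim(points))) {
    if (length(points) != 2L * N_LANDMARKS) {
      stop("landmark frame needs exactly 136 coordinates (got ",
           length(points), ")", call. = FALSE)
    }
    points <- matrix(points, ncol = 2L, byrow = TRUE)
  }
  points <- as.matrix(points)
  if (nrow(points) != N_LANDMARKS || ncol(points) != 2L) {
    stop("landmark frame must be a 68 x 2 matrix (got ",
         nrow(points), " x ", ncol(points), ")", call. = FALSE)
  }
  if (!all(is.finite(points))) {
    stop("landmark frame contains non-finite coordinates", call. = FALSE)
  }
  if (frame_index < 0) stop("frame_index must be non-negative", call. = FALSE)
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points,
            timestamp = as.numeric(timestamp),
            frame_index = as.integer(frame_index),
            class = c("landmark_frame", "matrix", "array"))
}

#' Construct a landmark stream
#'
#' A stream stores one row per frame: a frame index, a timestamp and the 136
#' flattened coordinates.  Frames are sorted by timestamp on construction;
#' timestamps drive all window assignment downstream, so dropped frames leave
#' gaps rather than shifting windows.
#'
#' @param frame_index integer vector of unique frame indices.
#' @param timestamp numeric vector of per-frame times, seconds.
#' @param coords n x 136 numeric matrix, columns x0, y0, ..., x67, y67.
#' @param fps nominal frame rate in frames per second (default 25).
#' @return a `landmark_stream` object.
#' @export
landmark_stream <- function(frame_index, timestamp, coords, fps = 25) {
  coords <- as.matrix(coords)
  if (length(frame_index) == 0L) {
    coords <- matrix(numeric(0), nrow = 0L, ncol = 2L * N_LANDMARKS)
  }
  if (ncol(coords) != 2L * N_LANDMARKS) {
    stop("coordinate matrix must have 136 columns (got ", ncol(coords), ")",
         call. = FALSE)
  }
  n <- nrow(coords)
  if (length(frame_index) != n || length(timestamp) != n) {
    stop("frame_index, timestamp and coords disagree on frame count",
         call. = FALSE)
  }
  if (anyDuplicated(frame_index)) {
    stop("frame_index values must be unique within a stream", call. = FALSE)
  }
  if (n > 0 && !all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1L, all))[1L]
    stop("non-finite coordinate in frame record ", bad, call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a positive scalar", call. = FALSE)
  }
  ord <- order(timestamp)
  storage.mode(coords) <- "double"
  colnames(coords) <- coord_names()
  structure(list(frame_index = as.integer(frame_index[ord]),
                 timestamp = as.numeric(timestamp[ord]),
                 coords = coords[ord, , drop = FALSE],
                 fps = as.numeric(fps)),
            class = "landmark_stream")
}

coord_names <- function() {
  as.vector(rbind(paste0("x", 0:67), paste0("y", 0:67)))
}

#' @export
length.landmark_stream <- function(x) length(x$timestamp)

#' @export
print.landmark_stream <- function(x, ...) {
  n <- length(x)
  cat("<landmark_stream> ", n, " frames @ ", x$fps, " fps nominal\n", sep = "")
  if (n > 0) {
    cat(sprintf("  t: %.3f .. %.3f s (%.1f s)\n",
                x$timestamp[1], x$timestamp[n],
                x$timestamp[n] - x$timestamp[1]))
  }
  invisible(x)
}

#' Extract one frame from a stream
#'
#' @param stream a `landmark_stream`.
#' @param i 1-based position in the stream.
#' @return a `landmark_frame`.
#' @export
get_frame <- function(stream, i) {
  stopifnot(inherits(stream, "landmark_stream"))
  if (i < 1L || i > length(stream)) stop("frame position out of range")
  landmark_frame(stream$coords[i, ],
                 timestamp = stream$timestamp[i],
                 frame_index = stream$frame_index[i])
}

#' Center of one eye's landmark block
#'
#' Arithmetic mean of the six points of the eye block.  Labels follow the
#' EAR formula literally: `"L"` is the 36-41 block and `"R"` the 42-47 block.
#' Note that in the standard 68-point scheme the 36-41 block is the
#' *subject's right* eye (image left); the formula's labels are kept as-is.
#'
#' @param frame a `landmark_frame` or 68 x 2 matrix.
#' @param eye `"L"` or `"R"`.
#' @return numeric length-2 vector (x, y).
#' @export
eye_center <- function(frame, eye = c("L", "R")) {
  eye <- match.arg(eye)
  idx <- if (eye == "L") EYE_L_IDX else EYE_R_IDX
  colMeans(landmark_pt(frame, idx))
}

## ---- readers / writers ----------------------------------------------------

#' Read a landmark stream from CSV or JSON-lines
#'
#' CSV layout: header `frame,t,x0,y0,...,x67,y67`, one row per video frame.
#' JSONL layout: one JSON object per line with the same keys.  Records with a
#' wrong coordinate count or non-finite values are rejected with an error
#' naming the offending record; the stream is never silently truncated.
#'
#' @param path file to read.
#' @param format `"csv"` or `"jsonl"`; default guesses from the extension.
#' @param fps nominal frame rate recorded on the returned stream.
#' @return a `landmark_stream`.
#' @export
read_landmark_stream <- function(path, format = NULL, fps = 25) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  format <- guess_format(path, format)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("frame", "t", coord_names())
    if (nrow(df) == 0L && length(df) == 0L) {
      stop("empty landmark file: ", path, call. = FALSE)
    }
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("landmark CSV lacks column(s): ",
           paste(utils::head(missing_cols, 3), collapse = ", "),
           call. = FALSE)
    }
    coords <- as.matrix(df[, coord_names(), drop = FALSE])
    landmark_stream(df$frame, df$t, coords, fps = fps)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      return(landmark_stream(integer(0), numeric(0),
                             matrix(numeric(0), 0, 136), fps = fps))
    }
    recs <- lapply(seq_along(lines), function(i) {
      obj <- jsonlite::fromJSON(lines[[i]])
      vals <- unlist(obj[coord_names()], use.names = FALSE)
      if (length(vals) != 136L || anyNA(vals)) {
        stop("malformed landmark record at line ", i, ": expected 136 finite ",
             "coordinates", call. = FALSE)
      }
      c(obj$frame, obj$t, vals)
    })
    m <- do.call(rbind, recs)
    landmark_stream(m[, 1L], m[, 2L], m[, -(1:2), drop = FALSE], fps = fps)
  }
}

#' Write a landmark stream to CSV or JSON-lines
#'
#' Inverse of [read_landmark_stream()]: integer fields round-trip exactly and
#' coordinates round-trip within 1e-9.
#'
#' @param stream a `landmark_stream`.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`; default guesses from the extension.
#' @export
write_landmark_stream <- function(stream, path, format = NULL) {
  stopifnot(inherits(stream, "landmark_stream"))
  format <- guess_format(path, format)
  if (format == "csv") {
    df <- data.frame(frame = stream$frame_index, t = stream$timestamp)
    df <- cbind(df, as.data.frame(stream$coords))
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(length(stream))) {
      rec <- c(list(frame = stream$frame_index[i], t = stream$timestamp[i]),
               as.list(stream$coords[i, ]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(NULL)
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "jsonl")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
}
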