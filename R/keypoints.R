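#' Construct a keypoint sequence
#'
#' The raw input of everything downstream: per-frame positions of the 17
#' canonical joints plus per-joint confidence.
#'
#' Coordinate conventions: `image2d` uses the image frame (origin top-left,
#' y increasing downward; "height" in the biomechanical sense is `-y`);
#' `world3d` is right-handed with x lateral (positive toward the athlete's
#' left), y up and z anterior.
#'
#' @param coords Numeric array `T x 17 x D` with `D` 2 or 3.
#' @param conf Confidence matrix `T x 17` in `[0, 1]`; defaults to 1.
#' @param frame_rate Frames per second (default 60).
#' @param mode `"image2d"` or `"world3d"`.
#' @return An object of class `keypoint_sequence`.
#' @export
keypoint_sequence <- function(coords, conf = NULL, frame_rate = 60,
                              mode = c("world3d", "image2d")) {
  mode <- match.arg(mode)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 17L) {
    stop("coords must be a T x 17 x D array", call. = FALSE)
  }
  Tn <- dim(coords)[1]
  D <- dim(coords)[3]
  if (!D %in% 2:3) stop("coordinate dimension must be 2 or 3", call. = FALSE)
  if (mode == "world3d" && D != 3L) {
    stop("world3d sequences need 3 coordinates per joint", call. = FALSE)
  }
  if (Tn < 5L) stop("a keypoint sequence needs at least 5 frames (the ",
                    "sliding-window size)", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (is.null(conf)) conf <- matrix(1, Tn, 17)
  if (any(conf < 0 | conf > 1)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(coords = coords, conf = conf, frame_rate = frame_rate, mode = mode),
    class = "keypoint_sequence"
  )
}

#' @export
print.keypoint_sequence <- function(x, ...) {
  cat("Keypoint sequence: ", dim(x$coords)[1], " frames x 17 joints (",
      x$mode, ", ", x$frame_rate, " Hz)\n", sep = "")
  invisible(x)
}

#' Number of frames in a keypoint sequence
#' @param seq A `keypoint_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

# T x D coordinates of one named joint
joint_track <- function(seq, joint) {
  j <- match(joint, COCO17)
  if (is.na(j)) stop("unknown joint: ", joint, call. = FALSE)
  seq$coords[, j, , drop = TRUE]
}

#' Interpolate low-confidence keypoints
#'
#' Joints whose confidence falls below `floor` are treated as missing and
#' filled by linear temporal interpolation (constant extrapolation at the
#' sequence ends).  A joint missing in more than `max_missing` of the frames
#' is an error, mirroring the assessment pipeline's input contract.
#'
#' @param seq A `keypoint_sequence`.
#' @param floor Confidence floor (default 0.3).
#' @param max_missing Maximum tolerated missing fraction per joint (default 0.3).
#' @return The sequence with imputed coordinates and confidence set to `floor`
#'   at imputed frames.
#' @export
impute_keypoints <- function(seq, floor = 0.3, max_missing = 0.3) {
  Tn <- n_frames(seq)
  for (j in 1:17) {
    bad <- seq$conf[, j] < floor
    if (!any(bad)) next
    if (mean(bad) > max_missing) {
      stop("joint '", COCO17[j], "' is missing (confidence < ", floor,
           ") in more than ", round(100 * max_missing), "% of frames",
           call. = FALSE)
    }
    ok <- which(!bad)
    for (d in seq_len(dim(seq$coords)[3])) {
      seq$coords[bad, j, d] <- stats::approx(
        x = ok, y = seq$coords[ok, j, d], xout = which(bad), rule = 2
      )$y
    }
    seq$conf[bad, j] <- floor
  }
  seq
}

#' Read keypoints from COCO-style JSON
#'
#' Accepts the COCO keypoint dialect: a document with an `annotations` array
#' whose entries carry an `image_id` (frame index) and a flat `keypoints`
#' vector of 17 `(x, y, v)` triplets, `v` being the visibility/confidence.
#'
#' @param path JSON file path.
#' @param frame_rate Frames per second recorded in the sequence (default 60).
#' @return A `keypoint_sequence` in `image2d` mode.
#' @export
read_keypoints_coco <- function(path, frame_rate = 60) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann <- doc$annotations
  if (is.null(ann)) stop("COCO JSON: no 'annotations' field in ", path,
                         call. = FALSE)
  if (is.data.frame(ann)) {
    ids <- ann$image_id
    kps <- ann$keypoints
    if (!is.list(kps)) kps <- split(kps, seq_len(nrow(ann)))
  } else {
    ids <- vapply(ann, function(a) a$image_id, numeric(1))
    kps <- lapply(ann, function(a) unlist(a$keypoints))
  }
  ord <- order(ids)
  kps <- kps[ord]
  Tn <- length(kps)
  coords <- array(NA_real_, c(Tn, 17, 2))
  conf <- matrix(NA_real_, Tn, 17)
  for (t in seq_len(Tn)) {
    v <- as.numeric(unlist(kps[[t]]))
    if (length(v) != 51L) {
      stop("COCO JSON: annotation ", t, " has ", length(v) / 3,
           " keypoints; expected 17", call. = FALSE)
    }
    m <- matrix(v, ncol = 3, byrow = TRUE)
    coords[t, , 1] <- m[, 1]
    coords[t, , 2] <- m[, 2]
    conf[t, ] <- pmin(1, pmax(0, m[, 3] / max(1, max(m[, 3]))))
  }
  keypoint_sequence(coords, conf, frame_rate = frame_rate, mode = "image2d")
}

#' Write keypoints to COCO-style JSON
#'
#' @param seq A `keypoint_sequence` (2D; world sequences are projected by
#'   dropping depth and flipping y back to the image convention).
#' @param path Output path.
#' @export
write_keypoints_coco <- function(seq, path) {
  co <- seq$coords
  if (seq$mode == "world3d") {
    xy <- co[, , 1:2, drop = FALSE]
    xy[, , 2] <- -xy[, , 2]
    co <- xy
  }
  Tn <- dim(co)[1]
  ann <- lapply(seq_len(Tn), function(t) {
    trip <- as.vector(t(cbind(co[t, , 1], co[t, , 2], seq$conf[t, ] * 2)))
    list(image_id = t, category_id = 1, keypoints = trip)
  })
  doc <- list(
    schema = "ttasym-coco/1",
    images = lapply(seq_len(Tn), function(t) list(id = t)),
    annotations = ann,
    categories = list(list(id = 1, name = "person", keypoints = COCO17))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read keypoints from the flat CSV dialect
#'
#' Columns: `frame, joint, x, y[, z], confidence`, with `joint` either a
#' canonical joint name or a 1-based index into the canonical ordering.
#'
#' @param path CSV path.
#' @param frame_rate Frames per second (default 60).
#' @return A `keypoint_sequence` (`world3d` if a `z` column is present,
#'   `image2d` otherwise).
#' @export
read_keypoints_csv <- function(path, frame_rate = 60) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint", "x", "y")
  if (!all(need %in% names(df))) {
    stop("keypoint CSV must have columns frame, joint, x, y[, z][, confidence]; ",
         "missing: ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  }
  has_z <- "z" %in% names(df)
  jidx <- if (is.numeric(df$joint)) as.integer(df$joint) else
    match(df$joint, COCO17)
  if (anyNA(jidx) || any(jidx < 1 | jidx > 17)) {
    stop("keypoint CSV: unknown joint identifier", call. = FALSE)
  }
  frames <- sort(unique(df$frame))
  Tn <- length(frames)
  nj <- length(unique(jidx))
  if (nj != 17L) {
    stop("keypoint CSV describes ", nj, " joints per frame; expected 17",
         call. = FALSE)
  }
  D <- if (has_z) 3L else 2L
  coords <- array(NA_real_, c(Tn, 17, D))
  conf <- matrix(1, Tn, 17)
  fidx <- match(df$frame, frames)
  coords[cbind(fidx, jidx, 1L)] <- df$x
  coords[cbind(fidx, jidx, 2L)] <- df$y
  if (has_z) coords[cbind(fidx, jidx, 3L)] <- df$z
  if ("confidence" %in% names(df)) conf[cbind(fidx, jidx)] <- df$confidence
  if (anyNA(coords)) {
    stop("keypoint CSV: some (frame, joint) cells are absent", call. = FALSE)
  }
  keypoint_sequence(coords, conf, frame_rate = frame_rate,
                    mode = if (has_z) "world3d" else "image2d")
}

#' Write keypoints to the flat CSV dialect
#'
#' @param seq A `keypoint_sequence`.
#' @param path Output path.
#' @export
write_keypoints_csv <- function(seq, path) {
  Tn <- n_frames(seq)
  D <- dim(seq$coords)[3]
  df <- data.frame(
    frame = rep(seq_len(Tn), each = 17),
    joint = rep(COCO17, Tn),
    x = as.vector(t(seq$coords[, , 1])),
    y = as.vector(t(seq$coords[, , 2]))
  )
  if (D == 3L) df$z <- as.vector(t(seq$coords[, , 3]))
  df$confidence <- as.vector(t(seq$conf))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
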