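#' Read a keypoint track from file
#'
#' Two on-disk formats are supported:
#' \describe{
#'   \item{`coco_json`}{COCO-style keypoint JSON: `images` with a
#'     `frame_index` per image, `annotations` with `bbox` as
#'     `[x, y, w, h]` (converted to corners at read) and `keypoints` as 22
#'     flattened (x, y, v) triplets, and a category carrying the skeleton's
#'     keypoint name list. Track metadata (passage id, fps, direction,
#'     grade label) lives under `info`.}
#'   \item{`csv`}{long format with columns
#'     `passage_id,frame,keypoint,x,y,visible,x2,y2`; one row per keypoint
#'     per frame plus a bbox row per frame (`keypoint = "__bbox__"`, corners
#'     in `x,y,x2,y2`). Metadata is carried in `#`-prefixed header comments
#'     (`# fps=30` etc.).}
#' }
#' Coordinates are returned as recorded (raw image pixels, y down);
#' visibility flags are preserved and frames are sorted by index.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"coco_json"`, or `"csv"`.
#' @return A [passage_track()] in raw image coordinates.
#' @seealso [write_track()], [canonicalize_track()]
#' @export
read_track <- function(path, format = c("auto", "coco_json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco_json" else "csv"
  if (format == "coco_json") read_track_coco(path) else read_track_csv(path)
}

read_track_coco <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  imgs <- doc$images
  anns <- doc$annotations
  if (is.null(anns) || length(anns) == 0L) stop("no frames in ", path)
  img_frame <- vapply(imgs, function(im) as.integer(im$frame_index), 0L)
  names(img_frame) <- vapply(imgs, function(im) as.character(im$id), "")

  n <- length(anns)
  kp <- array(NA_real_, c(n, 22L, 2L))
  vis <- matrix(FALSE, n, 22L)
  bbox <- matrix(NA_real_, n, 4L)
  fidx <- integer(n)
  for (i in seq_len(n)) {
    a <- anns[[i]]
    kk <- unlist(a$keypoints)
    if (length(kk) != 66L)
      stop(sprintf("schema error: frame %s has %d keypoints, expected 22",
                   as.character(a$image_id), length(kk) %/% 3L))
    m <- matrix(kk, ncol = 3L, byrow = TRUE)
    kp[i, , 1] <- m[, 1]; kp[i, , 2] <- m[, 2]
    vis[i, ] <- m[, 3] > 0
    bb <- unlist(a$bbox)
    if (length(bb) != 4L)
      stop("schema error: malformed bbox at frame ", as.character(a$image_id))
    bbox[i, ] <- c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])
    fidx[i] <- img_frame[[as.character(a$image_id)]]
  }
  if (anyDuplicated(fidx)) stop("schema error: duplicate frame_index")
  info <- doc$info
  passage_track(
    kp, vis, bbox, frame_index = fidx,
    fps = if (!is.null(info$fps)) info$fps else 30,
    direction = if (!is.null(info$direction)) info$direction else NA_character_,
    passage_id = if (!is.null(info$passage_id)) info$passage_id else "passage",
    label = if (!is.null(info$label)) info$label else NULL
  )
}

read_track_csv <- function(path) {
  hdr <- readLines(path, n = 50L)
  meta <- list(fps = 30, direction = NA_character_, label = NULL)
  for (ln in grep("^#", hdr, value = TRUE)) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key == "fps") meta$fps <- as.numeric(val)
      if (key == "direction" && nzchar(val)) meta$direction <- val
      if (key == "label" && nzchar(val)) meta$label <- as.numeric(val)
    }
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  need <- c("passage_id", "frame", "keypoint", "x", "y", "visible")
  if (!all(need %in% names(df)))
    stop("schema error: csv must have columns ", paste(need, collapse = ","))
  if (nrow(df) == 0L) stop("no frames in ", path)

  sk <- cow_skeleton()
  bb_rows <- df$keypoint == "__bbox__"
  bdf <- df[bb_rows, , drop = FALSE]
  pdf <- df[!bb_rows, , drop = FALSE]
  frames <- sort(unique(df$frame))
  n <- length(frames)
  if (nrow(bdf) != n) stop("schema error: expected one bbox row per frame")

  kp <- array(NA_real_, c(n, 22L, 2L))
  vis <- matrix(FALSE, n, 22L)
  bbox <- matrix(NA_real_, n, 4L)
  fi <- match(pdf$frame, frames)
  ki <- match(pdf$keypoint, sk$names)
  if (anyNA(ki))
    stop("schema error: unknown keypoint ",
         paste(unique(pdf$keypoint[is.na(ki)]), collapse = ", "))
  cnt <- table(factor(fi, levels = seq_len(n)))
  if (any(cnt != 22L))
    stop(sprintf("schema error: frame %s has %d keypoints, expected 22",
                 frames[which(cnt != 22L)[1]], cnt[which(cnt != 22L)[1]]))
  kp[cbind(fi, ki, 1L)] <- pdf$x
  kp[cbind(fi, ki, 2L)] <- pdf$y
  vis[cbind(fi, ki)] <- as.logical(pdf$visible)
  bi <- match(bdf$frame, frames)
  bbox[bi, ] <- cbind(bdf$x, bdf$y, bdf$x2, bdf$y2)

  passage_track(kp, vis, bbox, frame_index = frames, fps = meta$fps,
                direction = meta$direction,
                passage_id = as.character(df$passage_id[1]),
                label = meta$label)
}

#' Write a keypoint track to file
#'
#' Inverse of [read_track()]; a read-write-read round trip reproduces the
#' track exactly in both formats.
#'
#' @param track a [passage_track()].
#' @param path output file path.
#' @param format `"auto"` (by extension), `"coco_json"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("auto", "coco_json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "coco_json" else "csv"
  if (format == "coco_json") write_track_coco(track, path)
  else write_track_csv(track, path)
  invisible(path)
}

write_track_coco <- function(track, path) {
  sk <- cow_skeleton()
  n <- n_frames(track)
  images <- lapply(seq_len(n), function(i) list(
    id = i, file_name = sprintf("frame_%06d.jpg", track$frame_index[i]),
    frame_index = track$frame_index[i]))
  annotations <- lapply(seq_len(n), function(i) {
    m <- cbind(track$kp[i, , 1], track$kp[i, , 2],
               ifelse(track$vis[i, ], 2L, 0L))
    bb <- track$bbox[i, ]
    list(id = i, image_id = i, category_id = 1L,
         bbox = c(bb[1], bb[2], bb[3] - bb[1], bb[4] - bb[2]),
         keypoints = as.vector(t(m)))
  })
  doc <- list(
    info = list(passage_id = track$passage_id, fps = track$fps,
                direction = track$direction, label = track$label),
    images = images,
    annotations = annotations,
    categories = list(list(id = 1L, name = "cow", keypoints = sk$names))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

write_track_csv <- function(track, path) {
  sk <- cow_skeleton()
  n <- n_frames(track)
  pdf <- data.frame(
    passage_id = track$passage_id,
    frame = rep(track$frame_index, each = 22L),
    keypoint = rep(sk$names, times = n),
    x = as.vector(t(matrix(track$kp[, , 1], nrow = n))),
    y = as.vector(t(matrix(track$kp[, , 2], nrow = n))),
    visible = as.vector(t(track$vis)),
    x2 = NA_real_, y2 = NA_real_
  )
  bdf <- data.frame(
    passage_id = track$passage_id, frame = track$frame_index,
    keypoint = "__bbox__",
    x = track$bbox[, 1], y = track$bbox[, 2],
    visible = TRUE, x2 = track$bbox[, 3], y2 = track$bbox[, 4]
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%.10g", track$fps), con)
  writeLines(sprintf("# direction=%s",
                     ifelse(is.na(track$direction), "", track$direction)), con)
  writeLines(sprintf("# label=%s",
                     if (is.null(track$label)) "" else format(track$label)), con)
  utils::write.csv(rbind(pdf, bdf), con, row.names = FALSE, quote = FALSE)
}
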