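#' Track particles through a time-lapse stack
#'
#' Detects particles in every frame (thresholding + 8-connected particle
#' measurement) and links them frame to frame by nearest-neighbour
#' assignment with a maximum link distance and one-frame gap closing.
#' Ambiguous links -- two candidate partners within 10 percent of the same
#' distance -- are rejected and the track is split, so crossing particles
#' are not silently swapped.  Track speed is the total path length over
#' elapsed time (the kymograph-style speed of a motile organelle); the
#' net-displacement speed is reported alongside.
#'
#' @param stack an [ImageStack-class].
#' @param max_link_um maximum displacement between consecutive frames
#'   (um); gap-closed links over two frames may span twice this.
#' @param min_track_frames discard tracks observed in fewer frames.
#' @param threshold_method,level thresholding per frame (see
#'   [binarizeImage()]).
#' @param min_area_um2 ignore detections smaller than this (noise specks).
#' @return A [TrackSet-class].
#' @export
trackParticles <- function(stack, max_link_um, min_track_frames = 5L,
                           threshold_method = "otsu", level = NULL,
                           min_area_um2 = 0.05) {
  stopifnot(is(stack, "ImageStack"), max_link_um > 0)
  ps <- stack@pixel_size_um
  n_frames <- length(stack@frames)
  if (n_frames < 2) stop("tracking requires at least 2 frames")
  detections <- lapply(seq_len(n_frames), function(f) {
    mask <- binarizeImage(stack@frames[[f]], threshold_method, level)
    df <- particleData(measureParticles(mask, ps, image_id = as.character(f)))
    df[df$area_um2 >= min_area_um2, c("centroid_row", "centroid_col"),
       drop = FALSE]
  })

  # active track state: list of (positions matrix, last_frame)
  active <- list()
  done <- list()
  for (f in seq_len(n_frames)) {
    det <- detections[[f]]
    used <- rep(FALSE, nrow(det))
    if (length(active)) {
      # candidate links: active tracks (gap <= 1 frame) x detections
      cand <- do.call(rbind, lapply(seq_along(active), function(ti) {
        tr <- active[[ti]]
        gap <- f - tr$last_frame
        if (gap > 2) return(NULL)
        last <- tr$positions[nrow(tr$positions), c("row", "col")]
        if (!nrow(det)) return(NULL)
        d_px <- sqrt((det$centroid_row - last[1])^2 +
                     (det$centroid_col - last[2])^2)
        data.frame(track = ti, det = seq_len(nrow(det)),
                   dist_um = d_px * ps, gap = gap)
      }))
      linked_tracks <- integer(0)
      if (!is.null(cand) && nrow(cand)) {
        cand <- cand[cand$dist_um <= max_link_um * cand$gap, , drop = FALSE]
        cand <- cand[order(cand$dist_um), , drop = FALSE]
        while (nrow(cand)) {
          top <- cand[1, ]
          # ambiguity: another candidate for the same track or detection
          # within 10% of this distance
          rivals <- cand[-1, , drop = FALSE]
          rivals <- rivals[(rivals$track == top$track |
                            rivals$det == top$det) &
                           rivals$dist_um <= top$dist_um * 1.1, ,
                           drop = FALSE]
          if (nrow(rivals)) {
            # reject the contested track/detection entirely (track splits)
            cand <- cand[cand$track != top$track & cand$det != top$det, ,
                         drop = FALSE]
            next
          }
          tr <- active[[top$track]]
          tr$positions <- rbind(tr$positions,
                                c(frame = f,
                                  row = det$centroid_row[top$det],
                                  col = det$centroid_col[top$det]))
          tr$last_frame <- f
          active[[top$track]] <- tr
          used[top$det] <- TRUE
          linked_tracks <- c(linked_tracks, top$track)
          cand <- cand[cand$track != top$track & cand$det != top$det, ,
                       drop = FALSE]
        }
      }
      # retire tracks not linked for more than one frame
      stale <- vapply(active, function(tr) f - tr$last_frame >= 2,
                      logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    # unmatched detections start new tracks
    for (di in which(!used)) {
      active[[length(active) + 1]] <- list(
        positions = matrix(c(f, det$centroid_row[di], det$centroid_col[di]),
                           1, 3, dimnames = list(NULL,
                                                 c("frame", "row", "col"))),
        last_frame = f)
    }
  }
  done <- c(done, active)

  keep <- vapply(done, function(tr) nrow(tr$positions) >= min_track_frames,
                 logical(1))
  done <- done[keep]
  dt <- stack@frame_interval_s
  rows <- lapply(seq_along(done), function(i) {
    posmat <- done[[i]]$positions
    steps_px <- sqrt(diff(posmat[, "row"])^2 + diff(posmat[, "col"])^2)
    elapsed <- (posmat[nrow(posmat), "frame"] - posmat[1, "frame"]) * dt
    path_um <- sum(steps_px) * ps
    net_um <- sqrt((posmat[nrow(posmat), "row"] - posmat[1, "row"])^2 +
                   (posmat[nrow(posmat), "col"] - posmat[1, "col"])^2) * ps
    data.frame(id = i, n_frames = nrow(posmat),
               start_frame = posmat[1, "frame"],
               path_length_um = path_um,
               speed_um_per_s = path_um / elapsed,
               net_speed_um_per_s = net_um / elapsed)
  })
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), n_frames = integer(0),
               start_frame = integer(0), path_length_um = numeric(0),
               speed_um_per_s = numeric(0), net_speed_um_per_s = numeric(0))
  new("TrackSet", tracks = tracks,
      positions = lapply(done, function(tr) tr$positions),
      frame_interval_s = dt, pixel_size_um = ps)
}
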