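#' Write a session to disk
#'
#' Lays a session out as a directory of grayscale PNG frames plus a CSV
#' manifest (`frame_index`, `filename`, `posture`, `partner_id`) and a JSON
#' partner schedule — the same layout [readSession()] accepts for
#' user-supplied data.
#'
#' @param session a [Session-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nFrames(session)
  fn <- sprintf("frame_%06d.png", session@frameIndex)
  for (i in seq_len(n))
    png::writePNG(session@frames[[i]], file.path(dir, fn[i]))
  utils::write.csv(
    data.frame(frame_index = session@frameIndex, filename = fn,
               posture = session@posture, partner_id = session@partner),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(schedule = session@schedule, seed = session@seed),
    file.path(dir, "schedule.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session from disk
#'
#' Reads the layout written by [writeSession()]: PNG frames named in a CSV
#' manifest, with the partner schedule rebuilt from the labels (and checked
#' against the stored schedule when one is present).
#'
#' @param dir session directory.
#' @return A [Session-class].
#' @export
readSession <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"))
  man <- man[order(man$frame_index), ]
  frames <- lapply(file.path(dir, man$filename), function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
  seed <- NA_integer_
  sj <- file.path(dir, "schedule.json")
  if (file.exists(sj)) {
    stored <- jsonlite::read_json(sj, simplifyVector = TRUE)
    if (!is.null(stored$seed)) seed <- as.integer(stored$seed)
  }
  .new_session(frames, man$posture, man$partner_id, man$frame_index, seed)
}
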