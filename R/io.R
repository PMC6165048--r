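#' Write a PVT session to a directory of plain-text files
#'
#' Writes `trace.csv` (`time_s,left_dist_px,right_dist_px`), `rt.csv`
#' (`stimulus_time_s,rt_ms`), `meta.json` (subject, PVT, tag, rates, seed)
#' and, for synthetic sessions, `latent.csv` with the latent drowsiness
#' series. Values round-trip through [read_session()] to better than 1e-9.
#'
#' @param session A [`pvt_session`][simulate_session].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(time_s = session$time_s,
               left_dist_px = session$left_dist,
               right_dist_px = session$right_dist),
    file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(session$rt, file.path(dir, "rt.csv"), row.names = FALSE)
  meta <- list(subject_id = session$subject_id, pvt_id = session$pvt_id,
               tag = session$tag, fps = session$fps,
               duration_s = session$duration_s, seed = session$seed)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  if (!is.null(session$latent))
    utils::write.csv(data.frame(latent = session$latent),
                     file.path(dir, "latent.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a PVT session from a directory
#'
#' @param dir Directory written by [write_session()] (or following the same
#'   layout).
#' @return A [`pvt_session`][simulate_session] object.
#' @export
read_session <- function(dir) {
  trace_f <- file.path(dir, "trace.csv")
  rt_f <- file.path(dir, "rt.csv")
  meta_f <- file.path(dir, "meta.json")
  for (f in c(trace_f, rt_f, meta_f))
    if (!file.exists(f)) stop("missing session file: ", f)
  tr <- utils::read.csv(trace_f)
  need <- c("time_s", "left_dist_px", "right_dist_px")
  if (!all(need %in% names(tr)))
    stop("trace.csv must have columns ", paste(need, collapse = ", "))
  bad <- which(diff(tr$time_s) <= 0)
  if (length(bad))
    stop("non-monotone timestamps in trace.csv at row ", bad[1] + 1)
  rt <- utils::read.csv(rt_f)
  if (!all(c("stimulus_time_s", "rt_ms") %in% names(rt)))
    stop("rt.csv must have columns stimulus_time_s, rt_ms")
  if (any(rt$rt_ms <= 0) || any(!is.finite(rt$rt_ms)))
    stop("rt.csv has nonpositive or non-finite RT at row ",
         which(rt$rt_ms <= 0 | !is.finite(rt$rt_ms))[1])
  if (is.unsorted(rt$stimulus_time_s))
    rt <- rt[order(rt$stimulus_time_s), , drop = FALSE]
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  meta$fps <- as.numeric(meta$fps)
  meta$duration_s <- as.numeric(meta$duration_s)
  latent_f <- file.path(dir, "latent.csv")
  latent <- if (file.exists(latent_f)) utils::read.csv(latent_f)$latent else NULL
  structure(list(
    subject_id = meta$subject_id, pvt_id = meta$pvt_id, tag = meta$tag,
    fps = meta$fps, duration_s = meta$duration_s,
    time_s = tr$time_s, left_dist = tr$left_dist_px,
    right_dist = tr$right_dist_px, rt = rt, latent = latent,
    blink_log = NULL, seed = meta$seed
  ), class = "pvt_session")
}

#' Write a cohort of sessions under one directory
#'
#' Each session goes to `<dir>/<subject>_<pvt>/`.
#'
#' @param sessions List of sessions.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sessions, dir) {
  for (s in sessions)
    write_session(s, file.path(dir, paste0(s$subject_id, "_", s$pvt_id)))
  invisible(dir)
}

#' Read all sessions found under a directory
#'
#' @param dir Directory containing session subdirectories.
#' @return List of sessions, sorted by (subject, PVT).
#' @export
read_cohort <- function(dir) {
  dirs <- list.dirs(dir, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "meta.json"))]
  if (length(dirs) == 0) stop("no sessions found under ", dir)
  sessions <- lapply(sort(dirs), read_session)
  sessions
}
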