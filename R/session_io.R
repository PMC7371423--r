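#' Construct a trial table
#'
#' The per-trial behavioral record of a whole learning run. \code{trial_index}
#' is the 0-based global ordinal across days (the learning axis is cumulative
#' trial number); lick times are seconds relative to stimulus onset.
#'
#' @param mouse_id character scalar or vector.
#' @param trial_index 0-based, strictly increasing, gapless integers.
#' @param day session ordinal per trial.
#' @param stimulus_freq_hz stimulus frequency per trial, Hz.
#' @param stimulus_class "go" or "no-go" per trial.
#' @param lick_times_s list of numeric vectors (possibly empty) per trial.
#' @param outcome optional; if omitted, derived with [classify_outcomes()].
#'   If supplied it is validated against the lick evidence.
#' @param response_window lick-counting window (seconds), default (1, 4]:
#'   stimulus offset plus a 3 s virtual response window.
#' @return a \code{data.frame} of class \code{trial_table} with columns
#'   mouse_id, trial_index, day, stimulus_freq_hz, stimulus_class, outcome,
#'   lick_times_s (list column) and first_lick_s.
#' @export
trial_table <- function(mouse_id, trial_index, day, stimulus_freq_hz,
                        stimulus_class, lick_times_s, outcome = NULL,
                        response_window = .RESPONSE_WINDOW) {
  n <- length(trial_index)
  if (n > 0 && (any(diff(trial_index) != 1L) || trial_index[1] != 0L))
    stop("trial_index must be 0-based, strictly increasing and gapless",
         call. = FALSE)
  if (!all(stimulus_class %in% c("go", "no-go")))
    stop("unknown stimulus_class (must be 'go' or 'no-go')", call. = FALSE)
  stopifnot(length(lick_times_s) == n)
  tab <- data.frame(
    mouse_id = rep_len(as.character(mouse_id), n),
    trial_index = as.integer(trial_index),
    day = rep_len(as.integer(day), n),
    stimulus_freq_hz = rep_len(as.numeric(stimulus_freq_hz), n),
    stimulus_class = as.character(stimulus_class),
    stringsAsFactors = FALSE)
  tab$lick_times_s <- lapply(lick_times_s, as.numeric)
  tab$first_lick_s <- vapply(tab$lick_times_s,
                             function(l) if (length(l)) min(l) else NA_real_,
                             numeric(1))
  attr(tab, "response_window") <- response_window
  class(tab) <- c("trial_table", "data.frame")
  derived <- classify_outcomes(tab)
  if (is.null(outcome)) {
    tab$outcome <- derived
  } else {
    bad <- which(outcome != derived)
    if (length(bad))
      stop("outcome inconsistent with lick evidence at trial_index: ",
           paste(tab$trial_index[bad], collapse = ", "), call. = FALSE)
    tab$outcome <- as.character(outcome)
  }
  out <- tab[, c("mouse_id", "trial_index", "day", "stimulus_freq_hz",
                 "stimulus_class", "outcome", "lick_times_s",
                 "first_lick_s")]
  attr(out, "response_window") <- response_window  # dropped by `[`
  class(out) <- c("trial_table", "data.frame")
  out
}

.TRIAL_CSV_COLS <- c("mouse_id", "trial_index", "day", "stimulus_freq_hz",
                     "stimulus_class", "outcome", "lick_times_s")

#' Write / read a trial table as CSV
#'
#' Columns are exactly \code{mouse_id,trial_index,day,stimulus_freq_hz,
#' stimulus_class,outcome,lick_times_s}; lick times are serialised as a
#' semicolon-joined list in one cell (empty cell = no licks). Reading
#' re-validates the outcome column against the lick evidence and errors
#' listing offending trial indices.
#'
#' @param table a \code{trial_table}.
#' @param path CSV file path.
#' @return \code{write_trial_table} returns \code{path} invisibly;
#'   \code{read_trial_table} returns a \code{trial_table}.
#' @export
write_trial_table <- function(table, path) {
  out <- as.data.frame(table)[, c("mouse_id", "trial_index", "day",
                                  "stimulus_freq_hz", "stimulus_class",
                                  "outcome")]
  out$lick_times_s <- vapply(table$lick_times_s, function(l)
    paste(formatC(l, format = "g", digits = 15), collapse = ";"),
    character(1))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  header <- names(data.table::fread(path, nrows = 0, data.table = FALSE))
  missing_cols <- setdiff(.TRIAL_CSV_COLS, header)
  if (length(missing_cols))
    stop("trial table CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- data.table::fread(path, colClasses = list(character = "lick_times_s"),
                           data.table = FALSE)
  licks <- lapply(raw$lick_times_s, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  trial_table(raw$mouse_id, raw$trial_index, raw$day, raw$stimulus_freq_hz,
              raw$stimulus_class, licks, outcome = raw$outcome)
}

#' Construct a trial-aligned photometry session
#'
#' @param traces numeric matrix, trials x frames.
#' @param time_s frame times in seconds relative to stimulus onset (0 =
#'   onset), uniformly spaced at 1/sampling_rate.
#' @param sampling_rate Hz.
#' @param baseline_window per-trial baseline (seconds); for task sessions it
#'   must end at or before the visual cue (-2 s).
#' @param mouse_id character scalar.
#' @param normalized logical flag: are traces dF/F (TRUE) or raw (FALSE)?
#' @param labels optional per-trial label data.frame (e.g. passive-tuning
#'   freq_hz / atten_db).
#' @return list of class \code{photometry_session}.
#' @export
photometry_session <- function(traces, time_s, sampling_rate,
                               baseline_window, mouse_id = "m1",
                               normalized = FALSE, labels = NULL) {
  traces <- as.matrix(traces)
  if (ncol(traces) != length(time_s))
    stop("shape mismatch: traces has ", ncol(traces),
         " frames but time_s has length ", length(time_s), call. = FALSE)
  dt <- diff(time_s)
  if (length(dt) && max(abs(dt - 1 / sampling_rate)) > 1e-6)
    stop("time_s must be uniformly spaced at 1/sampling_rate", call. = FALSE)
  if (baseline_window[1] >= baseline_window[2])
    stop("baseline_window must be increasing", call. = FALSE)
  if (!is.null(labels) && nrow(labels) != nrow(traces))
    stop("labels must have one row per trial", call. = FALSE)
  structure(list(mouse_id = mouse_id, traces = traces,
                 time_s = as.numeric(time_s), sampling_rate = sampling_rate,
                 baseline_window = as.numeric(baseline_window),
                 normalized = isTRUE(normalized), labels = labels),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %s: %d trials x %d frames @ %g Hz, %s\n",
              x$mouse_id, nrow(x$traces), ncol(x$traces), x$sampling_rate,
              if (x$normalized) "dF/F" else "raw"))
  invisible(x)
}

#' Write / read a photometry session (plain-text container)
#'
#' Sessions are stored as a JSON sidecar \code{<stem>.json} holding the time
#' axis and attributes (sampling_rate, normalized, baseline_window,
#' mouse_id, labels) plus a headerless CSV matrix \code{<stem>_traces.csv}.
#' The round trip is bit-exact.
#'
#' @param session a \code{photometry_session}.
#' @param stem file stem; the two files are \code{<stem>.json} and
#'   \code{<stem>_traces.csv}.
#' @return \code{write_session} returns \code{stem} invisibly;
#'   \code{read_session} a \code{photometry_session}.
#' @export
write_session <- function(session, stem) {
  meta <- list(mouse_id = session$mouse_id,
               sampling_rate = exact_chr(session$sampling_rate),
               normalized = session$normalized,
               baseline_window = exact_chr(session$baseline_window),
               time_s = exact_chr(session$time_s),
               labels = session$labels)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  write_num_csv(session$traces, paste0(stem, "_traces.csv"))
  invisible(stem)
}

# doubles as %.17g strings: the round trip through text is bit-exact
exact_chr <- function(x) formatC(x, format = "g", digits = 17)

write_num_csv <- function(mat, path) {
  chr <- exact_chr(as.matrix(mat))
  dim(chr) <- dim(as.matrix(mat))
  data.table::fwrite(data.table::as.data.table(chr), path,
                     col.names = FALSE, quote = FALSE)
}

#' @rdname write_session
#' @export
read_session <- function(stem) {
  meta_path <- paste0(stem, ".json")
  if (!file.exists(meta_path)) stop("no session metadata at ", meta_path,
                                    call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (attr_name in c("sampling_rate", "normalized", "time_s"))
    if (is.null(meta[[attr_name]]))
      stop("session metadata is missing attribute '", attr_name, "'",
           call. = FALSE)
  traces <- as.matrix(data.table::fread(paste0(stem, "_traces.csv"),
                                        header = FALSE, data.table = FALSE,
                                        colClasses = "numeric"))
  dimnames(traces) <- NULL
  labels <- if (is.data.frame(meta$labels)) meta$labels else NULL
  photometry_session(traces, as.numeric(meta$time_s),
                     as.numeric(meta$sampling_rate),
                     as.numeric(meta$baseline_window),
                     mouse_id = meta$mouse_id,
                     normalized = meta$normalized, labels = labels)
}

#' Construct a body-camera frame stack
#'
#' @param frames integer array trials x frames x height x width (8-bit
#'   grayscale values 0--255).
#' @param time_s frame times (seconds relative to stimulus onset).
#' @param frame_rate Hz (default 30, the body-camera rate).
#' @param roi_masks named list of logical height x width masks (e.g.
#'   forelimbs, neck, jaw); each must be nonempty.
#' @return list of class \code{frame_stack}.
#' @export
frame_stack <- function(frames, time_s, frame_rate, roi_masks) {
  d <- dim(frames)
  if (length(d) != 4L) stop("frames must be a 4-D array", call. = FALSE)
  if (d[2] != length(time_s))
    stop("frame count does not match time_s", call. = FALSE)
  if (is.null(names(roi_masks)) || any(!nzchar(names(roi_masks))))
    stop("roi_masks must be a named list", call. = FALSE)
  for (nm in names(roi_masks)) {
    m <- roi_masks[[nm]]
    if (!any(m)) stop("ROI '", nm, "' is empty", call. = FALSE)
    if (!all(dim(m) == d[3:4]))
      stop("ROI '", nm, "' does not match the image size", call. = FALSE)
  }
  structure(list(frames = frames, time_s = as.numeric(time_s),
                 frame_rate = frame_rate, roi_masks = roi_masks),
            class = "frame_stack")
}

#' Write / read a frame stack (plain-text container)
#'
#' \code{<stem>.json} holds the time axis, frame rate and array shape;
#' \code{<stem>_frames.csv} holds one flattened frame per row (row-major over
#' height then width); \code{<stem>_roi_<name>.csv} hold 0/1 masks.
#'
#' @param stack a \code{frame_stack}.
#' @param stem file stem.
#' @return \code{write_frames} returns \code{stem} invisibly;
#'   \code{read_frames} a \code{frame_stack}.
#' @export
write_frames <- function(stack, stem) {
  d <- dim(stack$frames)
  meta <- list(shape = d, frame_rate = exact_chr(stack$frame_rate),
               time_s = exact_chr(stack$time_s),
               rois = names(stack$roi_masks))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(aperm(stack$frames, c(4, 3, 2, 1)), ncol = d[3] * d[4],
                 byrow = TRUE)
  data.table::fwrite(data.table::as.data.table(flat),
                     paste0(stem, "_frames.csv"), col.names = FALSE)
  for (nm in names(stack$roi_masks))
    data.table::fwrite(
      data.table::as.data.table(stack$roi_masks[[nm]] * 1L),
      paste0(stem, "_roi_", nm, ".csv"), col.names = FALSE)
  invisible(stem)
}

#' @rdname write_frames
#' @export
read_frames <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (is.null(meta$frame_rate))
    stop("frame-stack metadata is missing attribute 'frame_rate'",
         call. = FALSE)
  d <- as.integer(meta$shape)
  flat <- as.matrix(data.table::fread(paste0(stem, "_frames.csv"),
                                      header = FALSE, data.table = FALSE))
  frames <- aperm(array(t(flat), dim = rev(d)), c(4, 3, 2, 1))
  rois <- lapply(stats::setNames(meta$rois, meta$rois), function(nm) {
    m <- as.matrix(data.table::fread(paste0(stem, "_roi_", nm, ".csv"),
                                     header = FALSE, data.table = FALSE))
    dimnames(m) <- NULL
    m > 0
  })
  frame_stack(frames, as.numeric(meta$time_s),
              as.numeric(meta$frame_rate), rois)
}

#' Cross-validate a behavioral / photometric / video bundle
#'
#' Report-only consistency checks: trial counts, monotone gapless
#' trial_index, time-axis alignment between photometry and frames. Never
#' mutates or errors; returns a machine-readable issue list.
#'
#' @param table a \code{trial_table}.
#' @param session a \code{photometry_session}.
#' @param frames optional \code{frame_stack}.
#' @return data.frame with columns \code{code} and \code{detail}; zero rows
#'   means the bundle is consistent.
#' @export
validate_bundle <- function(table, session, frames = NULL) {
  issues <- list()
  add <- function(code, detail)
    issues[[length(issues) + 1L]] <<- data.frame(code = code, detail = detail,
                                                 stringsAsFactors = FALSE)
  if (nrow(table) != nrow(session$traces))
    add("trial_count_mismatch",
        sprintf("table has %d trials, session has %d", nrow(table),
                nrow(session$traces)))
  dup <- table$trial_index[duplicated(table$trial_index)]
  if (length(dup))
    add("duplicate_trial_index", paste("trial_index", unique(dup),
                                       collapse = "; "))
  if (nrow(table) > 1 && any(diff(table$trial_index) <= 0))
    add("nonmonotone_trial_index",
        paste("first violation after trial_index",
              table$trial_index[which(diff(table$trial_index) <= 0)[1]]))
  if (session$baseline_window[2] > .VISUAL_CUE_S + 1e-9)
    add("baseline_after_cue",
        sprintf("baseline_window ends at %g s but the visual cue is at %g s",
                session$baseline_window[2], .VISUAL_CUE_S))
  if (!is.null(frames)) {
    if (dim(frames$frames)[1] != nrow(table))
      add("frame_trial_count_mismatch",
          sprintf("frames cover %d trials, table has %d",
                  dim(frames$frames)[1], nrow(table)))
    overlap <- min(frames$time_s[length(frames$time_s)],
                   session$time_s[length(session$time_s)]) -
      max(frames$time_s[1], session$time_s[1])
    if (overlap <= 0)
      add("frame_clock_misaligned",
          "frame and photometry time axes do not overlap")
  }
  if (!length(issues))
    return(data.frame(code = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
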