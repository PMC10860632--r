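# JSON and flat-CSV serialisation of single-unit recordings and cohorts.

#' Write a recording to JSON
#'
#' @param recording a [cell_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_recording <- function(recording, path) {
  stopifnot(inherits(recording, "cell_recording"))
  obj <- list(spike_times = recording$spike_times,
              epochs = recording$epochs,
              depth_um = recording$depth,
              receptive_field_mm = recording$receptive_field,
              animal = recording$animal, group = recording$group,
              true_class = attr(recording, "true_class"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a recording from JSON
#'
#' @param path JSON file written by [write_spike_recording()] or following
#'   the same schema (`spike_times`, `epochs` with kind/filament_index/
#'   onset/duration/trial, `depth_um`, `receptive_field_mm`).
#' @return A [cell_recording].
#' @export
read_spike_recording <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$spike_times) || is.null(obj$epochs))
    stop("recording JSON must contain 'spike_times' and 'epochs'")
  ep <- as.data.frame(obj$epochs, stringsAsFactors = FALSE)
  ep$filament_index <- suppressWarnings(as.integer(ep$filament_index))
  rf <- obj$receptive_field_mm
  if (!is.null(rf)) rf <- matrix(unlist(rf), ncol = 2,
                                 dimnames = list(NULL, c("x", "y")))
  rec <- cell_recording(as.numeric(obj$spike_times), ep,
                        depth = obj$depth_um %||% NA_real_,
                        receptive_field = rf,
                        animal = obj$animal %||% NA_character_,
                        group = obj$group %||% NA_character_)
  if (!is.null(obj$true_class)) attr(rec, "true_class") <- obj$true_class
  rec
}

#' Flat-CSV export of a recording
#'
#' Writes two plain CSV files next to `stem`: `<stem>_spikes.csv`
#' (column `time_s`) and `<stem>_epochs.csv` (the epoch table).
#'
#' @param recording a [cell_recording].
#' @param stem path stem without extension.
#' @return Character vector of the two paths, invisibly.
#' @export
write_spike_csv <- function(recording, stem) {
  stopifnot(inherits(recording, "cell_recording"))
  p1 <- paste0(stem, "_spikes.csv"); p2 <- paste0(stem, "_epochs.csv")
  utils::write.csv(data.frame(time_s = recording$spike_times), p1,
                   row.names = FALSE)
  utils::write.csv(recording$epochs, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write/read a tidy two-group table
#'
#' The stats stage consumes tidy CSV with columns `group`, `id`, `value`.
#'
#' @param a,b numeric vectors.
#' @param names group labels (control first).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(a, b, path, names = c("control", "comparison")) {
  df <- data.frame(group = rep(names, c(length(a), length(b))),
                   id = c(seq_along(a), seq_along(b)),
                   value = c(a, b), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("group", "value"), names(df))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "))
  # first-appearance order: the control group is written first
  split(df$value, factor(df$group, levels = unique(df$group)))
}
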