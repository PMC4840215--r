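#' Spike train
#'
#' The universal currency of the pipeline: sorted event times for one unit on
#' one electrode over a recording window. Times are seconds, double precision;
#' the window is half-open `[t_start, t_stop)`.
#'
#' @param times numeric vector of spike times (s); sorted internally.
#' @param electrode_id,unit_id labels. `unit_id` defaults to 1 (unsorted).
#' @param t_start,t_stop recording window (s), `t_stop > t_start`.
#' @return An object of class `spike_train`: a list with fields `times`,
#'   `electrode_id`, `unit_id`, `t_start`, `t_stop`.
#' @export
spike_train <- function(times, electrode_id = "e1", unit_id = 1L,
                        t_start = 0, t_stop = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  times <- sort(times)
  if (is.null(t_stop)) t_stop <- if (length(times)) max(times) + 1e-9 else t_start + 1
  if (t_stop <= t_start) stop("t_stop must exceed t_start")
  if (length(times) && (times[1] < t_start || times[length(times)] >= t_stop))
    stop("spike times must lie in [t_start, t_stop)")
  structure(list(times = times, electrode_id = as.character(electrode_id),
                 unit_id = unit_id, t_start = t_start, t_stop = t_stop),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s/u%s: %d spikes in [%g, %g) s, %.3g Hz>\n",
              x$electrode_id, x$unit_id, length(x$times), x$t_start, x$t_stop,
              train_rate(x)))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Mean firing rate of a spike train (Hz)
#' @param train a [spike_train()].
#' @export
train_rate <- function(train) {
  length(train$times) / (train$t_stop - train$t_start)
}

#' Restrict a spike train to a union of time windows
#'
#' Keeps spikes falling inside the union of half-open windows
#' `[start, end)`; spike times are preserved (no re-referencing), so
#' distances computed afterwards remain on the recording clock.
#'
#' @param train a [spike_train()].
#' @param windows two-column matrix (or data.frame) of window start/end
#'   times in seconds; overlapping windows are merged first.
#' @return a [spike_train()] containing only the retained spikes; the
#'   `t_start`/`t_stop` of the input are kept.
#' @export
extract_window_trains <- function(train, windows) {
  windows <- normalize_windows(windows)
  if (nrow(windows) == 0)
    return(spike_train(numeric(0), train$electrode_id, train$unit_id,
                       train$t_start, train$t_stop))
  keep <- rep(FALSE, length(train$times))
  for (i in seq_len(nrow(windows)))
    keep <- keep | (train$times >= windows[i, 1] & train$times < windows[i, 2])
  spike_train(train$times[keep], train$electrode_id, train$unit_id,
              train$t_start, train$t_stop)
}

#' Merge and sort a set of half-open windows
#' @param windows two-column matrix/data.frame of `[start, end)` windows.
#' @return matrix with non-overlapping sorted rows.
#' @keywords internal
normalize_windows <- function(windows) {
  windows <- as.matrix(windows)
  if (length(windows) == 0) return(matrix(numeric(0), ncol = 2))
  if (ncol(windows) != 2) stop("windows must have two columns (start, end)")
  windows <- windows[windows[, 2] > windows[, 1], , drop = FALSE]
  if (nrow(windows) == 0) return(matrix(numeric(0), ncol = 2))
  windows <- windows[order(windows[, 1]), , drop = FALSE]
  out <- windows[1, , drop = FALSE]
  for (i in seq_len(nrow(windows))[-1]) {
    k <- nrow(out)
    if (windows[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], windows[i, 2])
    else out <- rbind(out, windows[i, ])
  }
  unname(out)
}

#' Complement of a window set within a recording
#' @param windows two-column matrix of `[start, end)` windows.
#' @param t_start,t_stop bounds of the recording (s).
#' @return two-column matrix of the complementary windows.
#' @export
complement_windows <- function(windows, t_start, t_stop) {
  w <- normalize_windows(windows)
  w <- w[w[, 2] > t_start & w[, 1] < t_stop, , drop = FALSE]
  if (nrow(w) == 0) return(matrix(c(t_start, t_stop), ncol = 2))
  w[, 1] <- pmax(w[, 1], t_start); w[, 2] <- pmin(w[, 2], t_stop)
  starts <- c(t_start, w[, 2])
  ends <- c(w[, 1], t_stop)
  out <- cbind(starts, ends)
  unname(out[out[, 2] > out[, 1], , drop = FALSE])
}

#' Spike-event table from a list of spike trains
#' @param trains list of [spike_train()] objects.
#' @return data.frame with columns `electrode_id`, `unit_id`, `time_s`,
#'   sorted by time.
#' @export
trains_to_table <- function(trains) {
  if (length(trains) == 0)
    return(data.frame(electrode_id = character(0), unit_id = integer(0),
                      time_s = numeric(0)))
  tab <- do.call(rbind, lapply(trains, function(tr) {
    if (length(tr$times) == 0) return(NULL)
    data.frame(electrode_id = tr$electrode_id, unit_id = tr$unit_id,
               time_s = tr$times)
  }))
  if (is.null(tab))
    return(data.frame(electrode_id = character(0), unit_id = integer(0),
                      time_s = numeric(0)))
  tab <- tab[order(tab$time_s, tab$electrode_id), ]
  rownames(tab) <- NULL
  tab
}

#' Rebuild spike trains from a spike-event table
#' @param tab data.frame with columns `electrode_id`, `unit_id`, `time_s`.
#' @param t_start,t_stop recording window (s).
#' @return named list of [spike_train()] keyed `"<electrode>.<unit>"`.
#' @export
table_to_trains <- function(tab, t_start, t_stop) {
  if (nrow(tab) == 0) return(list())
  key <- paste(tab$electrode_id, tab$unit_id, sep = ".")
  out <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    spike_train(tab$time_s[idx], tab$electrode_id[idx[1]], tab$unit_id[idx[1]],
                t_start, t_stop)
  })
  out[order(names(out))]
}

#' Write / read a spike-event table as TSV
#'
#' Plain-text interchange format: header `electrode_id  unit_id  time_s`,
#' one row per spike, sorted by time.
#' @param trains list of spike trains (for writing).
#' @param path file path.
#' @rdname spike_tsv
#' @export
write_spike_tsv <- function(trains, path) {
  write.table(trains_to_table(trains), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @param t_start,t_stop recording window used to rebuild trains.
#' @rdname spike_tsv
#' @export
read_spike_tsv <- function(path, t_start, t_stop) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "numeric"))
  table_to_trains(tab, t_start, t_stop)
}
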