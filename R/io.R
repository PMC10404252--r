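# All tables are plain delimited text; datasets carry a JSON sidecar with
# the stimulus timing and panel metadata. Times are seconds relative to
# stimulus onset (onset = 0); bins are half-open.

#' Write / read a spike dataset as a long delimited table
#'
#' The table has columns `pn_id`, `odor_id`, `trial`, `spike_time_s`; a JSON
#' sidecar (`<path>.json`) stores the window spec, odor panel, trial count
#' and PN index so that a round trip reproduces the dataset.
#'
#' @param dataset A `spike_dataset`.
#' @param path File path for the table (tab-separated).
#' @return `write_spike_table()` returns `path` invisibly;
#'   `read_spike_table()` returns a `spike_dataset`.
#' @export
write_spike_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  readr::write_tsv(dataset$spikes, path)
  sidecar <- list(
    windows = dataset$windows,
    panel = dataset$panel,
    n_trials = dataset$n_trials,
    pn_ids = dataset$pn_ids %||% seq_len(dataset$n_pns)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) abort("Missing JSON sidecar for spike table.")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  spikes <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              pn_id = readr::col_integer(),
                              odor_id = readr::col_character(),
                              trial = readr::col_integer(),
                              spike_time_s = readr::col_double()
                            ))
  required <- c("pn_id", "odor_id", "trial", "spike_time_s")
  if (!all(required %in% names(spikes))) {
    abort("Spike table must have columns pn_id, odor_id, trial, spike_time_s.")
  }
  bad <- which(is.na(spikes$trial) | spikes$trial < 1)
  if (length(bad) > 0) {
    abort(sprintf("Invalid trial index at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad_t <- which(!is.finite(spikes$spike_time_s))
  if (length(bad_t) > 0) {
    abort(sprintf("Non-finite spike time at row(s): %s",
                  paste(head(bad_t, 5), collapse = ", ")))
  }
  windows <- purrr::map(meta$windows, as.numeric)
  pn_ids <- as.integer(meta$pn_ids)
  new_spike_dataset(
    spikes = spikes, panel = tibble::as_tibble(meta$panel),
    windows = windows, n_trials = as.integer(meta$n_trials),
    n_pns = length(pn_ids)
  ) |> (\(ds) { ds$pn_ids <- pn_ids; ds })()
}

#' Write / read a binary POR matrix
#'
#' Comma-separated table with a `locust_id` column and one 0/1 column per
#' odor (header row of odor ids).
#'
#' @param por A POR table (see [por_scores()]).
#' @param path File path (CSV).
#' @return `write_por_matrix()` returns `path` invisibly;
#'   `read_por_matrix()` returns a `por_matrix` tibble.
#' @export
write_por_matrix <- function(por, path) {
  stopifnot(is.data.frame(por))
  readr::write_csv(por, path)
  invisible(path)
}

#' @rdname write_por_matrix
#' @export
read_por_matrix <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(out) == 0) abort("Empty POR matrix (header-only file).")
  odor_cols <- setdiff(names(out), "locust_id")
  if (length(odor_cols) == 0) abort("POR matrix has no odor columns.")
  for (col in odor_cols) {
    bad <- which(!(out[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      abort(sprintf("Non-binary POR entry in column '%s', row(s): %s",
                    col, paste(head(bad, 5), collapse = ", ")))
    }
  }
  class(out) <- c("por_matrix", class(out))
  out
}

#' Write / read palp-separation traces
#'
#' Long-format CSV (`locust_id`, `odor_id`, `frame`, `time_s`,
#' `separation`) with a JSON sidecar storing onset/offset and frame rate.
#'
#' @param traces A `por_traces` table (see [simulate_por_traces()]).
#' @param path File path (CSV).
#' @return `write_trace_table()` returns `path` invisibly;
#'   `read_trace_table()` returns a `por_traces` tibble.
#' @export
write_trace_table <- function(traces, path) {
  stopifnot(is.data.frame(traces))
  readr::write_csv(tibble::as_tibble(traces), path)
  jsonlite::write_json(
    list(onset_s = attr(traces, "onset_s") %||% 0,
         offset_s = attr(traces, "offset_s") %||% 4,
         fps = attr(traces, "fps") %||% 30),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("locust_id", "odor_id", "frame", "time_s", "separation")
  if (!all(required %in% names(out))) {
    abort("Trace table must have columns locust_id, odor_id, frame, time_s, separation.")
  }
  bad <- which(out$separation < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative separation at row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(onset_s = 0, offset_s = 4, fps = 30)
  }
  structure(out, onset_s = meta$onset_s, offset_s = meta$offset_s,
            fps = meta$fps, class = c("por_traces", class(out)))
}

#' Write / read a synthetic-data configuration as JSON
#'
#' @param config A [synth_config()].
#' @param path File path (JSON).
#' @return `write_synth_config()` returns `path` invisibly;
#'   `read_synth_config()` returns a `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  obj <- unclass(config)
  obj$timing <- as.list(obj$timing)  # keep names through JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$odor_panel <- tibble::as_tibble(raw$odor_panel)
  raw$timing <- unlist(raw$timing)
  do.call(synth_config, raw)
}
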