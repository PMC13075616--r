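#' Multichannel recording container
#'
#' A `recording` holds a channel-by-sample signal matrix (microvolts) with a
#' sampling rate, per-channel modality and optional per-channel annotations
#' (depth-electrode shaft, contact index, gray-matter flag, region label)
#' used for bipolar derivation and region aggregation.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of unique channel labels.
#' @param modality `"scalp"` or `"intracranial"`, scalar or per channel.
#' @param annotations Optional data.frame with one row per channel; columns
#'   among `shaft`, `contact`, `gray_matter`, `roi`.
#' @param reference Reference state: `"raw"`, `"common_average"` or
#'   `"bipolar"`.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels, modality = "scalp",
                      annotations = NULL, reference = "raw") {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (length(labels) == 0L) stop("empty channel list")
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  if (length(labels) != nrow(data)) stop("labels do not match data rows")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  modality <- rep_len(modality, nrow(data))
  stopifnot(all(modality %in% c("scalp", "intracranial")))
  if (!is.null(annotations)) stopifnot(nrow(annotations) == nrow(data))
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 modality = modality, annotations = annotations,
                 reference = reference),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%s, %s)\n",
              nrow(x$data), ncol(x$data), x$fs,
              paste(unique(x$modality), collapse = "+"), x$reference))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)

duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Read / write a channel-to-region map
#'
#' The channel map links channel labels to atlas regions and hemisphere
#' side, and carries the depth-electrode bookkeeping (shaft, contact,
#' gray-matter flag) needed for bipolar derivation.
#'
#' @param path TSV file with columns `channel_label`, `roi`, `hemisphere`,
#'   `gray_matter`, `shaft`, `contact`.
#' @return A data.frame channel map.
#' @export
read_channel_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel_label", "roi")
  if (!all(need %in% names(map))) {
    stop("channel map must contain columns: ", paste(need, collapse = ", "))
  }
  map
}

#' @rdname read_channel_map
#' @param map Channel map data.frame.
#' @export
write_channel_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write event lists
#'
#' Events are stored as TSV with columns `onset_s`, `condition`
#' (`"IED"`/`"no_IED"`) and `label` (source or channel label). Times must
#' be sorted ascending.
#'
#' @param path TSV file path.
#' @return data.frame with the three columns above.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_s", "condition", "label") %in% names(ev)))
  if (is.unsorted(ev$onset_s)) stop("event times must be sorted ascending")
  ev
}

#' @rdname read_events
#' @param events Event data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
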