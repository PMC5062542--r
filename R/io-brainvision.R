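#' Write a recording as a BrainVision triplet
#'
#' Writes `<basename>.vhdr` / `.vmrk` / `.eeg`: an INI-style text header, a
#' text marker file with one stimulus marker per event, and multiplexed
#' IEEE-float-32 binary data in microvolts.
#'
#' @param recording a [continuous_recording()].
#' @param basename output path without extension.
#' @param marker_map named character vector mapping class labels to marker
#'   descriptions; default `c(low = "S  1", high = "S  2")`.
#' @return the header path, invisibly.
#' @export
write_brainvision <- function(recording, basename,
                              marker_map = c(low = "S  1", high = "S  2")) {
  stopifnot(inherits(recording, "continuous_recording"))
  base <- basename(basename)
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ncol(recording$data)),
    paste0("SamplingInterval=", format(1e6 / recording$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(ncol(recording$data)), recording$channel_labels)
  )
  writeLines(hdr, vhdr)

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(recording$events) > 0) {
    desc <- marker_map[recording$events$label]
    if (anyNA(desc)) rlang::abort("event label missing from `marker_map`")
    mk <- c(mk, sprintf(
      "Mk%d=Stimulus,%s,%d,1,0",
      seq_len(nrow(recording$events)) + 1L, desc, recording$events$onset
    ))
  }
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(recording$data)), con, size = 4)
  invisible(vhdr)
}

parse_bv_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && section != "") {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, the binary data file (IEEE-float-32 or INT-16
#' with per-channel resolution; multiplexed or vectorized orientation) and
#' the `.vmrk` stimulus markers.
#'
#' @param vhdr_path path to the `.vhdr` header.
#' @param marker_map named character vector mapping marker descriptions to
#'   class labels; default `c("S  1" = "low", "S  2" = "high")`. Unmapped
#'   stimulus markers are dropped with a warning.
#' @param eog_labels channel labels to assign the EOG role (default
#'   [default_eog_labels()]).
#' @return a [continuous_recording()].
#' @export
read_brainvision <- function(vhdr_path,
                             marker_map = c("S  1" = "low", "S  2" = "high"),
                             eog_labels = default_eog_labels()) {
  if (!file.exists(vhdr_path)) rlang::abort(paste0("no such file: ", vhdr_path))
  dirn <- dirname(vhdr_path)
  hdr <- parse_bv_ini(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")

  chinfo <- hdr[["Channel Infos"]]
  labels <- character(nch)
  resol <- rep(1, nch)
  for (k in seq_len(nch)) {
    parts <- strsplit(chinfo[[paste0("Ch", k)]], ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resol[k] <- as.numeric(parts[3])
  }

  eeg_path <- file.path(dirn, ci$DataFile)
  con <- file(eeg_path, "rb")
  on.exit(close(con), add = TRUE)
  nbytes <- file.info(eeg_path)$size
  if (fmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, numeric(), n = nbytes / 4, size = 4)
  } else if (fmt == "INT_16") {
    raw <- readBin(con, integer(), n = nbytes / 2, size = 2, signed = TRUE)
  } else {
    rlang::abort(paste0("unsupported BinaryFormat: ", fmt))
  }
  ns <- length(raw) %/% nch
  data <- if (orient == "MULTIPLEXED") {
    t(matrix(raw, nch, ns))
  } else {
    matrix(raw, ns, nch)
  }
  data <- sweep(data, 2, resol, "*")

  events <- tibble::tibble(onset = integer(), label = character())
  vmrk_path <- file.path(dirn, ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(vmrk_path)) {
    mi <- parse_bv_ini(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    rows <- purrr::compact(purrr::map(mi, function(v) {
      parts <- strsplit(v, ",", fixed = TRUE)[[1]]
      if (parts[1] != "Stimulus") return(NULL)
      list(desc = parts[2], onset = as.integer(parts[3]))
    }))
    if (length(rows) > 0) {
      desc <- unname(vapply(rows, `[[`, character(1), "desc"))
      onset <- unname(vapply(rows, `[[`, integer(1), "onset"))
      lab <- marker_map[desc]
      if (anyNA(lab)) {
        rlang::warn("dropping stimulus markers not present in `marker_map`")
      }
      keep <- !is.na(lab)
      events <- tibble::tibble(onset = onset[keep], label = unname(lab[keep]))
    }
  }

  roles <- ifelse(labels %in% unname(eog_labels), "EOG", "EEG")
  continuous_recording(data, fs, labels, roles, events)
}

#' Read / write an events table as CSV
#'
#' Plain two-column CSV (`onset_sample`, `label`) as an alternative event
#' source to `.vmrk` markers.
#'
#' @param path CSV path.
#' @param events tibble with columns `onset` and `label`.
#' @return `read_events_csv()` returns a tibble with columns `onset`,
#'   `label`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("onset_sample", "label") %in% names(df))) {
    rlang::abort("events CSV needs columns `onset_sample` and `label`")
  }
  tibble::tibble(onset = as.integer(df$onset_sample), label = as.character(df$label))
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(
    data.frame(onset_sample = events$onset, label = events$label),
    path, row.names = FALSE
  )
  invisible(path)
}
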