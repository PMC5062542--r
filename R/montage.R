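#' Approximate 2D scalp layout for a 32-channel 10-20 montage
#'
#' Returns idealized top-view coordinates (x: left -1 to right +1, y: posterior
#' -1 to anterior +1) for the standard 32-electrode actiCap-style montage used
#' by the synthetic generator. The coordinates are schematic - they serve to
#' parameterize abstract component topographies and blink decay, not a forward
#' head model.
#'
#' @param labels optional character vector; subset and order of channels to
#'   return. Defaults to the full 32-channel montage.
#' @return a tibble with columns `label`, `x`, `y`.
#' @export
#' @examples
#' montage_positions(c("Fz", "Cz", "Pz"))
montage_positions <- function(labels = NULL) {
  pos <- tibble::tribble(
    ~label,  ~x,    ~y,
    "Fp1", -0.31,  0.95,
    "Fp2",  0.31,  0.95,
    "F7",  -0.81,  0.59,
    "F3",  -0.43,  0.55,
    "Fz",   0.00,  0.52,
    "F4",   0.43,  0.55,
    "F8",   0.81,  0.59,
    "FC5", -0.68,  0.28,
    "FC1", -0.23,  0.26,
    "FC2",  0.23,  0.26,
    "FC6",  0.68,  0.28,
    "T7",  -1.00,  0.00,
    "C3",  -0.50,  0.00,
    "Cz",   0.00,  0.00,
    "C4",   0.50,  0.00,
    "T8",   1.00,  0.00,
    "TP9", -1.05, -0.33,
    "CP5", -0.68, -0.28,
    "CP1", -0.23, -0.26,
    "CP2",  0.23, -0.26,
    "CP6",  0.68, -0.28,
    "TP10", 1.05, -0.33,
    "P7",  -0.81, -0.59,
    "P3",  -0.43, -0.55,
    "Pz",   0.00, -0.52,
    "P4",   0.43, -0.55,
    "P8",   0.81, -0.59,
    "PO9", -0.42, -0.88,
    "O1",  -0.31, -0.95,
    "Oz",   0.00, -1.00,
    "O2",   0.31, -0.95,
    "PO10", 0.42, -0.88
  )
  if (is.null(labels)) return(pos)
  missing <- setdiff(labels, pos$label)
  if (length(missing) > 0) {
    rlang::abort(paste0("unknown montage labels: ", paste(missing, collapse = ", ")))
  }
  pos[match(labels, pos$label), ]
}

#' Default EEG channel labels (32-channel 10-20 montage)
#' @return character vector of 32 labels.
#' @export
default_eeg_labels <- function() montage_positions()$label

#' Default EOG channel labels
#'
#' Four electro-oculogram electrodes: left and right outer canthi (horizontal
#' pair) and above/below the left eye (vertical pair).
#' @return named character vector with names `left`, `right`, `above`, `below`.
#' @export
default_eog_labels <- function() {
  c(left = "HEOGL", right = "HEOGR", above = "VEOGU", below = "VEOGL")
}

# Gaussian scalp weighting centered at (x0, y0); max-abs normalized to 1.
# Used for abstract component / artifact topographies.
topo_gaussian <- function(labels, x0, y0, width) {
  pos <- montage_positions(labels)
  w <- exp(-((pos$x - x0)^2 + (pos$y - y0)^2) / (2 * width^2))
  w / max(abs(w))
}
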