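#' The speller alphabet
#'
#' The 28-symbol alphabet used by the shuffle speller: the 26 uppercase
#' letters, `"_"` (space) and `"<"` (backspace).
#'
#' @return A character vector of length 28.
#' @export
#' @examples
#' speller_alphabet()
speller_alphabet <- function() {
  c(LETTERS, "_", "<")
}

#' Stimulation frequency set for the four-box SSVEP interface
#'
#' Each of the four target boxes is flanked by an LED array flickering at a
#' distinct frequency, so attending a box elicits a classifiable steady-state
#' visual evoked potential (SSVEP) at that frequency and its harmonics.
#' Targets are ordered top, bottom, left, right.
#'
#' @param frequencies_hz Stimulation frequencies in Hz, one per target.
#'   Defaults to 8.0, 9.7, 11.3 and 13.0 Hz.
#' @param n_harmonics Number of harmonics (including the fundamental) used in
#'   the reference bank and the synthetic response. Default 2.
#' @return An object of class `ss_stimulus_set`: a list with elements
#'   `frequencies_hz`, `n_harmonics`, and `target_names`.
#' @export
#' @examples
#' stimulus_set()
stimulus_set <- function(frequencies_hz = c(8.0, 9.7, 11.3, 13.0),
                         n_harmonics = 2L) {
  if (!is.numeric(frequencies_hz) || length(frequencies_hz) != 4L ||
      any(frequencies_hz <= 0) || anyDuplicated(frequencies_hz) > 0L) {
    stop_invalid("`frequencies_hz` must be 4 distinct positive frequencies.")
  }
  check_number(n_harmonics, "n_harmonics", min = 1)
  structure(
    list(
      frequencies_hz = as.numeric(frequencies_hz),
      n_harmonics = as.integer(n_harmonics),
      target_names = c("top", "bottom", "left", "right")
    ),
    class = "ss_stimulus_set"
  )
}

#' @export
print.ss_stimulus_set <- function(x, ...) {
  cat("<ss_stimulus_set>\n")
  cat("  frequencies:",
      paste(sprintf("%s=%g Hz", x$target_names, x$frequencies_hz),
            collapse = ", "), "\n")
  cat("  harmonics:  ", x$n_harmonics, "\n")
  invisible(x)
}

#' Screen layout of the four-box speller
#'
#' Geometry of the four target boxes, the LED patches next to them, and the
#' small calibration targets, in degrees of visual angle.  The coordinate
#' origin is the screen centre, x to the right, y up.  Top and bottom boxes
#' are wide (15 deg x 7 deg), left and right boxes are tall
#' (6 deg x 18 deg), each flush against its screen edge; LED patches
#' (1.6 deg x 2.4 deg) sit just outside each box toward the screen edge,
#' and calibration targets (0.8 deg square) sit at the box centres.
#'
#' @param screen_deg Width and height of the usable screen area in degrees of
#'   visual angle. Default `c(30, 22)`.
#' @return An object of class `ss_screen_layout` with a `boxes` tibble
#'   (target, centre, half-sizes), `led_deg`, `calib_deg` and `screen_deg`.
#' @export
#' @examples
#' screen_layout()
screen_layout <- function(screen_deg = c(30, 22)) {
  if (!is.numeric(screen_deg) || length(screen_deg) != 2L ||
      any(screen_deg <= 0)) {
    stop_invalid("`screen_deg` must be two positive numbers.")
  }
  hw <- screen_deg[1] / 2
  hh <- screen_deg[2] / 2
  boxes <- tibble::tibble(
    target = c("top", "bottom", "left", "right"),
    cx = c(0, 0, -(hw - 3), hw - 3),
    cy = c(hh - 3.5, -(hh - 3.5), 0, 0),
    half_w = c(7.5, 7.5, 3, 3),
    half_h = c(3.5, 3.5, 9, 9)
  )
  structure(
    list(boxes = boxes, led_deg = c(1.6, 2.4), calib_deg = c(0.8, 0.8),
         screen_deg = as.numeric(screen_deg)),
    class = "ss_screen_layout"
  )
}

#' @export
print.ss_screen_layout <- function(x, ...) {
  cat("<ss_screen_layout> screen", paste(x$screen_deg, collapse = " x "),
      "deg\n")
  print(x$boxes)
  invisible(x)
}

# Centre of a target box, as c(x, y) in degrees
box_center <- function(layout, target) {
  b <- layout$boxes[target, , drop = FALSE]
  c(b$cx, b$cy)
}

# Which box (1..4) each gaze point falls in, or NA if none
point_in_box <- function(layout, x, y) {
  b <- layout$boxes
  hit <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(b))) {
    inside <- abs(x - b$cx[i]) <= b$half_w[i] & abs(y - b$cy[i]) <= b$half_h[i]
    hit[inside & is.na(hit)] <- i
  }
  hit
}
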