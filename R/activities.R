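#' Activity classes
#'
#' The eight activity classes recognised throughout the package, with their
#' fixed integer encoding. Seven are activities of daily living (ADLs); the
#' eighth is a fall. The encoding is stable: integer codes 0--7 in the order
#' below, used for one-hot encoding, confusion-matrix ordering and file
#' round-trips.
#'
#' | code | label            |
#' |-----:|------------------|
#' | 0    | walking          |
#' | 1    | jogging          |
#' | 2    | jumping          |
#' | 3    | going_upstairs   |
#' | 4    | going_downstairs |
#' | 5    | standing_up      |
#' | 6    | sitting_down     |
#' | 7    | falling          |
#'
#' @return `activity_labels()` returns the character vector of the eight
#'   labels in encoding order.
#' @examples
#' activity_labels()
#' activity_code("falling")
#' activity_from_code(0:7)
#' @export
activity_labels <- function() {
  c("walking", "jogging", "jumping", "going_upstairs", "going_downstairs",
    "standing_up", "sitting_down", "falling")
}

#' @rdname activity_labels
#' @param label character vector of activity labels.
#' @return `activity_code()` returns the integer code(s) (0-based).
#' @export
activity_code <- function(label) {
  idx <- match(label, activity_labels())
  if (anyNA(idx)) {
    stop("unknown activity label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' @rdname activity_labels
#' @param code integer vector of codes in 0..7.
#' @return `activity_from_code()` returns the label(s).
#' @export
activity_from_code <- function(code) {
  code <- as.integer(code)
  if (any(code < 0L | code > 7L, na.rm = TRUE)) {
    stop("activity codes must lie in 0..7", call. = FALSE)
  }
  activity_labels()[code + 1L]
}
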