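#' Lead tile layout of an ECG page
#'
#' Describes how a clean state image divides into the 12 per-lead patches.
#' Tiles are a `rows` x `cols` grid in row-major order; `lead_order[i]` names
#' the lead occupying tile `i`.  Explicit tile rectangles may be supplied for
#' report dialects whose tiles are not an exact grid.
#'
#' @param rows,cols Grid shape with `rows * cols == 12`.
#' @param lead_order Permutation of the 12 standard lead names.
#' @param tiles Optional list of 12 [crop_rect()]s overriding the derived grid.
#' @return Object of class `"lead_layout"`.
#' @export
lead_layout <- function(rows = 6L, cols = 2L, lead_order = TET_LEADS,
                        tiles = NULL) {
  if (rows * cols != 12) stop("lead layout must have rows * cols == 12")
  if (length(lead_order) != 12 || !setequal(lead_order, TET_LEADS))
    stop("lead_order must be a permutation of the 12 standard lead names")
  if (!is.null(tiles) && length(tiles) != 12)
    stop("explicit tiles must list exactly 12 rectangles")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 lead_order = lead_order, tiles = tiles),
            class = "lead_layout")
}

layout_tiles <- function(layout, H, W) {
  if (!is.null(layout$tiles)) return(layout$tiles)
  if (H %% layout$rows != 0 || W %% layout$cols != 0)
    stop(sprintf("image %dx%d does not divide into a %dx%d tile grid",
                 H, W, layout$rows, layout$cols))
  th <- H %/% layout$rows; tw <- W %/% layout$cols
  lapply(0:11, function(i) {
    r <- i %/% layout$cols; cc <- i %% layout$cols
    crop_rect(cc * tw, r * th, tw, th)
  })
}

#' Split a clean state image into 12 per-lead patches
#'
#' @param ecg_image Grayscale matrix (a preprocessed state image).
#' @param layout A [lead_layout()].
#' @return Named list of 12 patches in tile order, names from
#'   `layout$lead_order`.
#' @export
split_leads <- function(ecg_image, layout = lead_layout()) {
  stopifnot(inherits(layout, "lead_layout"))
  tiles <- layout_tiles(layout, nrow(ecg_image), ncol(ecg_image))
  patches <- lapply(tiles, function(rect) crop_region(ecg_image, rect))
  names(patches) <- layout$lead_order
  patches
}

#' Assemble the 36-channel multi-state input tensor
#'
#' Resizes each of the 3 x 12 patches to `target_size` x `target_size` by
#' area averaging, rescales intensities to `[0, 1]`, and stacks them with the
#' lead-major channel convention `c = 3 * (g - 1) + s` (1-based), where `g`
#' is the lead index in `lead_order` and `s` indexes the state in the order
#' pretest, exercise, recovery.  Channels of one lead are therefore
#' contiguous triples, which is what aligns the inter-state grouped
#' convolution's default 12 groups with leads.
#'
#' @param patches_by_state Named list (`pretest`, `exercise`, `recovery`) of
#'   12-patch lists as returned by [split_leads()].
#' @param target_size Output spatial size (default 224).
#' @return `target_size` x `target_size` x 36 array of class
#'   `"multi_state_tensor"` with values in `[0, 1]` and a `channels`
#'   attribute naming each channel `"<lead>.<state>"`.
#' @export
assemble_tensor <- function(patches_by_state, target_size = 224L) {
  if (!all(TET_STATES %in% names(patches_by_state)))
    stop("missing state(s): ",
         paste(setdiff(TET_STATES, names(patches_by_state)), collapse = ", "))
  for (s in TET_STATES)
    if (length(patches_by_state[[s]]) != 12)
      stop(sprintf("state %s has %d lead patches, expected 12", s,
                   length(patches_by_state[[s]])))
  lead_names <- names(patches_by_state[[1]])
  out <- array(0, dim = c(target_size, target_size, 36))
  ch_names <- character(36)
  for (g in 1:12) {
    for (s in 1:3) {
      patch <- patches_by_state[[TET_STATES[s]]][[g]]
      if (is.null(patch)) stop(sprintf("missing patch: lead %d, state %s",
                                       g, TET_STATES[s]))
      c_idx <- 3L * (g - 1L) + s
      v <- resample_box(patch, target_size, target_size) / 255
      out[, , c_idx] <- pmin(pmax(v, 0), 1)
      ch_names[c_idx] <- paste(if (is.null(lead_names)) g else lead_names[g],
                               TET_STATES[s], sep = ".")
    }
  }
  structure(out, channels = ch_names, class = "multi_state_tensor")
}

#' Disassemble a multi-state tensor back into per-lead, per-state patches
#'
#' Inverse of the channel packing of [assemble_tensor()] (patches come back
#' at the tensor's resolution, i.e. after the resize).
#'
#' @param tensor A `"multi_state_tensor"`.
#' @return Named list by state of 12-patch lists, values in `[0, 1]`.
#' @export
disassemble_tensor <- function(tensor) {
  out <- lapply(1:3, function(s)
    lapply(1:12, function(g) tensor[, , 3L * (g - 1L) + s]))
  names(out) <- TET_STATES
  out
}

#' Build the network input tensor for one patient report
#'
#' Convenience composition: preprocess the report, split each clean state
#' image into lead patches, and assemble the multi-state tensor.
#'
#' @param document Directory of page PNGs or list of page images.
#' @param input_size Tensor spatial size.
#' @param layout A [lead_layout()].
#' @param ... Passed to [preprocess_report()].
#' @return A `"multi_state_tensor"`.
#' @export
report_tensor <- function(document, input_size = 224L,
                          layout = lead_layout(), ...) {
  clean <- preprocess_report(document, ...)
  patches <- lapply(clean, split_leads, layout = layout)
  assemble_tensor(patches, target_size = input_size)
}
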