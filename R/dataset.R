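#' Build a training dataset from a synthetic cohort
#'
#' Runs the full input pipeline for every patient — render the three state
#' pages, crop, binarize, split into lead patches, assemble the 36-channel
#' multi-state tensor — and stores each sample compactly as an integer
#' `(input_size^2) x 36` matrix (values 0--255; rescaled to `[0, 1]` at
#' batch time).
#'
#' @param cohort A `"tet_cohort"` from [generate_cohort()].
#' @param input_size Tensor spatial size (112 for desk-scale runs, 224 for
#'   the published geometry).
#' @param spec A [binarization_spec()].
#' @param verbose Print progress every 50 patients.
#' @return List with `x` (list of sample matrices), `y` (label vector) and
#'   `metadata` (the cohort's metadata table).
#' @export
cohort_dataset <- function(cohort, input_size = 112L,
                           spec = binarization_spec(), verbose = FALSE) {
  stopifnot(inherits(cohort, "tet_cohort"))
  cfg <- cohort$config
  crop <- cohort_crop_rect(cfg)
  layout <- lead_layout(cfg$lead_rows, cfg$lead_cols)
  xs <- vector("list", length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    pages <- patient_pages(p, cfg)
    clean <- lapply(pages, function(pg)
      binarize(crop_region(pg, crop), spec))
    patches <- lapply(clean, split_leads, layout = layout)
    tensor <- assemble_tensor(patches, target_size = input_size)
    m <- matrix(as.integer(round(as.numeric(tensor) * 255)),
                input_size^2, 36)
    xs[[i]] <- m
    if (verbose && i %% 50 == 0) message("  prepared ", i, " patients")
  }
  list(x = xs, y = cohort$metadata$label, metadata = cohort$metadata)
}

# Crop rectangle matching the generator's page geometry: drop the banner
# strip and any unused remainder rows/columns so the lead grid divides
# exactly.
cohort_crop_rect <- function(cfg, banner_height = 60L) {
  W <- cfg$page_size[1]; H <- cfg$page_size[2]
  tile_h <- (H - banner_height) %/% cfg$lead_rows
  tile_w <- W %/% cfg$lead_cols
  crop_rect(0L, banner_height, tile_w * cfg$lead_cols, tile_h * cfg$lead_rows)
}
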