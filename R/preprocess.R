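#' Rectangular crop region
#'
#' Coordinates are 0-based with the origin at the top-left pixel and the
#' rectangle half-open on its right and bottom edges, so `crop_rect(0, 0, w, h)`
#' covers a whole `h` x `w` image.
#'
#' @param left,top Integer pixel offsets of the top-left corner (0-based).
#' @param width,height Positive integer extent in pixels.
#' @return An object of class `"crop_rect"`.
#' @export
crop_rect <- function(left, top, width, height) {
  v <- c(left = left, top = top, width = width, height = height)
  if (any(v != round(v))) stop("crop_rect coordinates must be integers")
  if (width <= 0 || height <= 0) stop("crop_rect width and height must be positive")
  if (left < 0 || top < 0) stop("crop_rect offsets must be nonnegative")
  structure(as.list(as.integer(round(v))), names = names(v), class = "crop_rect")
}

#' Crop an image to a rectangle
#'
#' @param image Grayscale matrix (rows y, columns x) or H x W x 3 color array.
#' @param rect A [crop_rect()]. Must lie fully inside the image; no clamping.
#' @return The cropped image, `rect$height` x `rect$width`.
#' @export
crop_region <- function(image, rect) {
  stopifnot(inherits(rect, "crop_rect"))
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (rect$left + rect$width > W || rect$top + rect$height > H)
    stop(sprintf("crop rectangle [%d,%d %dx%d] exceeds image bounds %dx%d",
                 rect$left, rect$top, rect$width, rect$height, W, H))
  rows <- (rect$top + 1):(rect$top + rect$height)
  cols <- (rect$left + 1):(rect$left + rect$width)
  if (length(d) == 3) image[rows, cols, , drop = FALSE] else image[rows, cols, drop = FALSE]
}

#' Convert a color image to grayscale
#'
#' Uses the ITU-R BT.601 luma weights, `round(0.299 R + 0.587 G + 0.114 B)`.
#' Single-plane input passes through unchanged.
#'
#' @param image H x W x 3 array or H x W matrix with values in 0--255.
#' @return H x W grayscale matrix.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) == 2) return(image)
  if (length(d) != 3 || d[3] != 3) stop("expected a matrix or an H x W x 3 array")
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' Binarization specification
#'
#' @param threshold Integer cut in 0--255.
#' @param polarity `"trace_dark_on_white"` (default: values above the threshold
#'   become white background 255, values at or below become trace 0) or
#'   `"trace_light_on_black"` for the inverse mapping.
#' @return An object of class `"binarization_spec"`.
#' @export
binarization_spec <- function(threshold = 128,
                              polarity = c("trace_dark_on_white", "trace_light_on_black")) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 255)
    stop("threshold must be a single value in 0..255")
  structure(list(threshold = threshold, polarity = match.arg(polarity)),
            class = "binarization_spec")
}

#' Threshold a grayscale image to black and white
#'
#' @param gray Single-plane matrix, values 0--255.
#' @param spec A [binarization_spec()].
#' @return Matrix with values in `{0, 255}` only.
#' @export
binarize <- function(gray, spec = binarization_spec()) {
  stopifnot(inherits(spec, "binarization_spec"))
  if (length(dim(gray)) != 2) stop("binarize expects a single-plane image")
  above <- gray > spec$threshold
  out <- gray
  if (spec$polarity == "trace_dark_on_white") {
    out[above] <- 255; out[!above] <- 0
  } else {
    out[above] <- 0; out[!above] <- 255
  }
  out
}

# Area-average (box) resampling weight matrix: rows are output pixels, columns
# input pixels; entry = fractional overlap of the output pixel's source
# interval with the input pixel, normalised so rows sum to 1.
box_weights <- local({
  cache <- new.env(parent = emptyenv())
  function(n_in, n_out) {
    key <- paste(n_in, n_out)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- box_weights_compute(n_in, n_out)
    cache[[key]]
  }
})

box_weights_compute <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * scale; b <- i * scale
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      ov <- min(b, j) - max(a, j - 1)
      if (ov > 0) A[i, j] <- ov / scale
    }
  }
  A / rowSums(A)   # guard rounding: every output pixel is an exact average
}

#' Resize an image by area averaging
#'
#' Each output pixel is the average of the source region it covers (a box
#' filter with fractional pixel coverage), the natural choice for binary trace
#' images where the result is the local trace coverage fraction.
#'
#' @param image Grayscale matrix.
#' @param height,width Output size in pixels.
#' @return `height` x `width` matrix.
#' @export
resample_box <- function(image, height, width) {
  Ar <- box_weights(nrow(image), height)
  Ac <- box_weights(ncol(image), width)
  Ar %*% image %*% t(Ac)
}

#' Normalize raw extracted text for keyword matching
#'
#' Lowercases and strips every character other than `a-z` and `0-9`
#' (including whitespace), so hyphenated or spaced variants of a state
#' keyword still match as substrings.
#'
#' @param raw Character vector.
#' @return Character vector of the same length.
#' @export
normalize_text <- function(raw) {
  gsub("[^a-z0-9]", "", tolower(raw))
}

#' Match a TET state keyword in normalized text
#'
#' Returns the first state keyword (priority order pretest, exercise,
#' recovery) occurring as a substring, or `NA` if none does.
#'
#' @param normalized Text already passed through [normalize_text()].
#' @return One of `"pretest"`, `"exercise"`, `"recovery"`, or `NA_character_`.
#' @export
match_state_keyword <- function(normalized) {
  vapply(normalized, function(txt) {
    for (kw in TET_STATES) if (grepl(kw, txt, fixed = TRUE)) return(kw)
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Identify which report page belongs to which TET state
#'
#' @param pages List of page images.
#' @param text_extractor Function mapping a page image to raw text. Use
#'   [glyph_text_extractor()] for pages rendered by this package, or
#'   [sidecar_text_extractor()] / a custom OCR adapter.
#' @return Named integer vector `c(pretest=, exercise=, recovery=)` of
#'   1-based page indices (first matching page wins).
#' @export
identify_state_pages <- function(pages, text_extractor = glyph_text_extractor()) {
  found <- c(pretest = NA_integer_, exercise = NA_integer_, recovery = NA_integer_)
  for (i in seq_along(pages)) {
    kw <- match_state_keyword(normalize_text(text_extractor(pages[[i]])))
    if (!is.na(kw) && is.na(found[[kw]])) found[[kw]] <- i
  }
  missing <- names(found)[is.na(found)]
  if (length(missing))
    stop("no page found for state(s): ", paste(missing, collapse = ", "))
  found
}

#' Text extractor that reads the renderer's banner glyphs
#'
#' Decodes the bitmap glyphs stamped into a page's banner region by
#' [render_state_page()] via exact template matching against the package's
#' built-in 5x7 font, giving a self-contained stand-in for an OCR engine on
#' synthetic pages.
#'
#' @param banner_height Height in pixels of the banner strip searched.
#' @return A function mapping a page image to the decoded text.
#' @export
glyph_text_extractor <- function(banner_height = 60) {
  function(page) {
    gray <- to_grayscale(page)
    banner <- gray[seq_len(min(banner_height, nrow(gray))), , drop = FALSE]
    decode_glyphs(banner)
  }
}

#' Text extractor stub reading sidecar truth
#'
#' For pages carrying a `truth_state` attribute (as produced by the synthetic
#' generator) or accompanied by a `*.truth.json` sidecar file, returns the
#' recorded state string instead of running any character recognition.
#'
#' @return A function mapping a page image to its true state text.
#' @export
sidecar_text_extractor <- function() {
  function(page) {
    st <- attr(page, "truth_state")
    if (!is.null(st)) return(st)
    src <- attr(page, "source_file")
    if (!is.null(src)) {
      sidecar <- paste0(sub("\\.png$", "", src), ".truth.json")
      if (file.exists(sidecar))
        return(jsonlite::read_json(sidecar)$state[[1]])
    }
    stop("page has no sidecar truth attached")
  }
}

#' Load report pages from a directory of page images
#'
#' Reads every PNG in `document` (or accepts an in-memory list of page
#' matrices) and rescales each page to `target_size` with area averaging.
#' Pages already at the target size pass through unscaled.
#'
#' @param document Directory containing page PNGs, or a list of page images.
#' @param target_size `c(width, height)` in pixels; default the conventional
#'   report page resolution 1080 x 640.
#' @return List of page images (grayscale matrices), each `height x width`,
#'   in file order, with `source_file` attributes when read from disk.
#' @export
render_report <- function(document, target_size = c(1080, 640)) {
  if (is.character(document)) {
    if (!dir.exists(document)) stop("cannot read document: ", document)
    files <- sort(list.files(document, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("document contains no pages: ", document)
    pages <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , seq_len(min(3, dim(img)[3]))]
      g <- to_grayscale(round(img * 255))
      attr(g, "source_file") <- f
      g
    })
  } else if (is.list(document)) {
    if (!length(document)) stop("document contains no pages")
    pages <- document
  } else stop("document must be a directory path or a list of page images")
  lapply(pages, function(p) {
    g <- to_grayscale(p)
    if (nrow(g) == target_size[2] && ncol(g) == target_size[1]) return(g)
    out <- round(resample_box(g, target_size[2], target_size[1]))
    attributes(out) <- c(attributes(out),
                         attributes(g)[c("source_file", "truth_state")])
    out
  })
}

#' Preprocess a TET report into clean state-labeled ECG images
#'
#' Runs the full preprocessing chain: page loading/rescaling, state
#' identification from extracted text, cropping to the ECG plot region,
#' grayscale conversion, and binarization.
#'
#' @param document Directory of page PNGs or list of page images.
#' @param crop A [crop_rect()] selecting the ECG region; default matches the
#'   synthetic renderer's banner/plot split at 1080 x 640.
#' @param spec A [binarization_spec()].
#' @param text_extractor Page-to-text function; see [identify_state_pages()].
#' @param target_size Page size before cropping, `c(width, height)`.
#' @return Named list `pretest`, `exercise`, `recovery` of binary images of
#'   the crop size, in that fixed order.
#' @export
preprocess_report <- function(document,
                              crop = default_crop_rect(),
                              spec = binarization_spec(),
                              text_extractor = glyph_text_extractor(),
                              target_size = c(1080, 640)) {
  pages <- render_report(document, target_size)
  idx <- identify_state_pages(pages, text_extractor)
  out <- lapply(TET_STATES, function(s) {
    page <- pages[[idx[[s]]]]
    binarize(to_grayscale(crop_region(page, crop)), spec)
  })
  names(out) <- TET_STATES
  out
}

#' Default ECG-region crop for generator-layout pages
#'
#' Drops the 60-pixel banner strip and the 4 unused bottom rows of a
#' 1080 x 640 page, leaving the 1080 x 576 plot region that divides exactly
#' into the default 6 x 2 lead grid.
#'
#' @return A [crop_rect()].
#' @export
default_crop_rect <- function() crop_rect(0L, 60L, 1080L, 576L)
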