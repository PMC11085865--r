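# Minimal 5x7 bitmap font for the state-keyword banner.  Only the letters
# appearing in the three keywords are defined; the renderer stamps them and
# the glyph text extractor decodes them by exact template matching, so the
# page-identification path can run end to end without an OCR engine.

GLYPHS <- local({
  def <- list(
    c = c(".XXX.",
          "X...X",
          "X....",
          "X....",
          "X....",
          "X...X",
          ".XXX."),
    e = c("XXXXX",
          "X....",
          "X....",
          "XXXX.",
          "X....",
          "X....",
          "XXXXX"),
    i = c("..X..",
          ".....",
          "..X..",
          "..X..",
          "..X..",
          "..X..",
          "..X.."),
    o = c(".XXX.",
          "X...X",
          "X...X",
          "X...X",
          "X...X",
          "X...X",
          ".XXX."),
    p = c("XXXX.",
          "X...X",
          "X...X",
          "XXXX.",
          "X....",
          "X....",
          "X...."),
    r = c("XXXX.",
          "X...X",
          "X...X",
          "XXXX.",
          "X.X..",
          "X..X.",
          "X...X"),
    s = c(".XXXX",
          "X....",
          "X....",
          ".XXX.",
          "....X",
          "....X",
          "XXXX."),
    t = c("XXXXX",
          "..X..",
          "..X..",
          "..X..",
          "..X..",
          "..X..",
          "..X.."),
    v = c("X...X",
          "X...X",
          "X...X",
          "X...X",
          ".X.X.",
          ".X.X.",
          "..X.."),
    x = c("X...X",
          "X...X",
          ".X.X.",
          "..X..",
          ".X.X.",
          "X...X",
          "X...X"),
    y = c("X...X",
          "X...X",
          ".X.X.",
          "..X..",
          "..X..",
          "..X..",
          "..X..")
  )
  lapply(def, function(rows) {
    do.call(rbind, lapply(strsplit(rows, ""), function(r) r == "X"))
  })
})

# Logical ink bitmap for a word at integer scale (letters 5 wide + 1 spacer).
word_bitmap <- function(word, scale = 1L) {
  letters <- strsplit(word, "")[[1]]
  unknown <- setdiff(letters, names(GLYPHS))
  if (length(unknown))
    stop("glyph not in font: ", paste(unknown, collapse = ", "))
  cols <- lapply(seq_along(letters), function(i) {
    g <- GLYPHS[[letters[i]]]
    if (i < length(letters)) cbind(g, matrix(FALSE, 7, 1)) else g
  })
  bm <- do.call(cbind, cols)
  if (scale > 1L) bm <- bm %x% matrix(1, scale, scale) > 0
  bm
}

# Stamp `text` into a grayscale page matrix at (top, left), 0-based offsets.
stamp_text <- function(image, text, top, left, scale = 4L, value = 0) {
  bm <- word_bitmap(text, scale)
  rows <- top + seq_len(nrow(bm)); cols <- left + seq_len(ncol(bm))
  if (max(rows) > nrow(image) || max(cols) > ncol(image))
    stop("text does not fit in the image at the requested position")
  sub <- image[rows, cols]
  sub[bm] <- value
  image[rows, cols] <- sub
  image
}

# Crop a logical matrix to its TRUE bounding box (NULL if empty).
ink_bbox <- function(ink) {
  rs <- which(rowSums(ink) > 0); cs <- which(colSums(ink) > 0)
  if (!length(rs)) return(NULL)
  ink[min(rs):max(rs), min(cs):max(cs), drop = FALSE]
}

# Decode banner ink by exact template matching against the three state
# keywords at scales 1..8; returns the decoded word or "".
decode_glyphs <- function(banner) {
  ink <- banner < 128
  got <- ink_bbox(ink)
  if (is.null(got)) return("")
  for (kw in TET_STATES) {
    for (scale in 1:8) {
      tmpl <- ink_bbox(word_bitmap(kw, scale))
      if (identical(dim(got), dim(tmpl)) && all(got == tmpl)) return(kw)
    }
  }
  ""
}
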