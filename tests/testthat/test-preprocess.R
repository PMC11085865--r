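test_that("text normalization lowercases and strips non-alphanumerics", {
  expect_equal(normalize_text("PRE-TEST  Stage 1!"), "preteststage1")
  expect_equal(normalize_text(""), "")
  expect_equal(normalize_text("Recovery 01:30"), "recovery0130")
})

test_that("state keyword matching uses substring search with fixed priority", {
  expect_equal(match_state_keyword("preteststage1"), "pretest")
  expect_equal(match_state_keyword("xyz123"), NA_character_)
  expect_equal(match_state_keyword("recoveryafterpretest"), "pretest")
  expect_equal(match_state_keyword(c("aexerciseb", "recovery")),
               c("exercise", "recovery"))
})

test_that("state pages are identified in any page order; absences are named", {
  rep <- tiny_report()
  pages <- unname(rep$pages)
  stub <- sidecar_text_extractor()
  expect_equal(identify_state_pages(pages, stub),
               c(pretest = 1L, exercise = 2L, recovery = 3L))
  shuffled <- pages[c(3, 1, 2)]   # recovery, pretest, exercise
  expect_equal(identify_state_pages(shuffled, stub),
               c(pretest = 2L, exercise = 3L, recovery = 1L))
  expect_error(identify_state_pages(pages[1:2], stub), "recovery")
})

test_that("the glyph extractor decodes rendered banners like the sidecar", {
  rep <- tiny_report()
  glyph <- glyph_text_extractor()
  for (s in c("pretest", "exercise", "recovery"))
    expect_equal(glyph(rep$pages[[s]]), s)
})

test_that("cropping is exact index arithmetic with no clamping", {
  img <- matrix(1:16, 4, 4)     # column-major ramp
  expect_identical(crop_region(img, crop_rect(0, 0, 4, 4)), img)
  sub <- crop_region(img, crop_rect(1, 1, 2, 2))
  expect_identical(sub, img[2:3, 2:3])
  expect_error(crop_region(img, crop_rect(3, 0, 2, 2)), "bounds")
  expect_error(crop_rect(0, 0, 0, 2), "positive")
})

test_that("grayscale conversion uses the BT.601 weights and passes gray through", {
  white <- array(255, dim = c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))
  red <- array(0, dim = c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(as.numeric(to_grayscale(red)), 76)  # round(0.299 * 255)
  g <- matrix(0:3, 2, 2)
  expect_identical(to_grayscale(g), g)
})

test_that("crop and grayscale commute exactly", {
  set.seed(3)
  img <- array(sample(0:255, 6 * 8 * 3, TRUE), dim = c(6, 8, 3))
  r <- crop_rect(2, 1, 4, 3)
  expect_identical(to_grayscale(crop_region(img, r)),
                   crop_region(to_grayscale(img), r))
})

test_that("binarization maps around the threshold and is idempotent", {
  expect_true(all(binarize(matrix(200, 3, 3)) == 255))
  x <- matrix(c(10, 120, 200, 90), 2, 2, byrow = TRUE)
  expect_equal(binarize(x, binarization_spec(128)),
               matrix(c(0, 0, 255, 0), 2, 2, byrow = TRUE))
  inv <- binarize(x, binarization_spec(128, "trace_light_on_black"))
  expect_equal(inv, 255 - binarize(x, binarization_spec(128)))
  set.seed(4)
  y <- matrix(sample(0:255, 100, TRUE), 10, 10)
  s <- binarization_spec(77)
  expect_identical(binarize(binarize(y, s), s), binarize(y, s))
  expect_error(binarization_spec(300), "0..255")
})

test_that("binarization removes every grid pixel of a rendered page", {
  rep <- tiny_report()
  page <- rep$pages$recovery
  bin <- binarize(page, binarization_spec())
  expect_equal(sum(bin == 0), sum(page == 0))       # trace + text kept
  expect_true(all(bin[page == 220] == 255))          # grid gone
})

test_that("area resampling agrees with a direct block-average oracle", {
  set.seed(5)
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  down <- resample_box(img, 8, 8)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- mean(img[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(down, oracle)
  # rows of the weight matrix always sum to 1 (fractional overlap case)
  A <- tetdia:::box_weights_compute(97, 37)
  expect_equal(rowSums(A), rep(1, 37))
})

test_that("render_report passes through at target size and rescales otherwise", {
  rep <- tiny_report()
  pages <- render_report(unname(rep$pages))
  expect_identical(pages[[1]], rep$pages$pretest)
  big <- matrix(runif(32 * 32, 0, 255), 32, 32)
  small <- render_report(list(big), target_size = c(16, 16))[[1]]
  expect_equal(small, round(resample_box(big, 16, 16)))
  expect_error(render_report(list()), "no pages")
  expect_error(render_report(tempfile()), "cannot read")
})

test_that("preprocess_report composes the pipeline in fixed state order", {
  rep <- tiny_report()
  shuffled <- unname(rep$pages)[c(2, 3, 1)]
  out <- preprocess_report(shuffled)
  expect_named(out, c("pretest", "exercise", "recovery"))
  expect_equal(dim(out$pretest), c(576, 1080))
  expect_true(all(unlist(out) %in% c(0, 255)))
  # matches a hand-composed pipeline for each state
  for (s in names(out)) {
    manual <- binarize(to_grayscale(crop_region(rep$pages[[s]],
                                                default_crop_rect())),
                       binarization_spec())
    expect_equal(unname(out[[s]]), unname(manual))
  }
  expect_error(preprocess_report(unname(rep$pages)[1:2]), "recovery")
})

test_that("state identification matches sidecar truth on shuffled reports", {
  set.seed(8)
  cfg <- cohort_config(n_patients = 5, prevalence = 0.4, seed = 21)
  co <- generate_cohort(cfg)
  stub <- sidecar_text_extractor()
  for (p in co$patients) {
    pages <- unname(patient_pages(p, cfg))
    perm <- sample(3)
    idx <- identify_state_pages(pages[perm], stub)
    truth <- vapply(pages[perm], attr, "", "truth_state")
    for (s in c("pretest", "exercise", "recovery"))
      expect_identical(truth[idx[[s]]], s)
  }
})
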