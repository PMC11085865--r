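test_that("noiseless trace at 60 bpm is exactly periodic with one-second period", {
  p <- waveform_params(heart_rate_bpm = c(pretest = 60, exercise = 120,
                                          recovery = 90),
                       noise_sd = 0, duration_s = 2, sampling_rate = 250)
  tr <- synth_beat(p, "pretest")
  expect_length(tr, 500)
  expect_equal(tr[1:250], tr[251:500])
})

test_that("ST offset changes only the ST-segment samples", {
  base <- waveform_params(noise_sd = 0)
  shifted <- base
  shifted$st_offset <- c(pretest = -0.2, exercise = -0.2, recovery = -0.2)
  t0 <- synth_beat(base, "pretest")
  t1 <- synth_beat(shifted, "pretest")
  d <- t1 - t0
  changed <- which(d != 0)
  expect_gt(length(changed), 0)
  # all changed samples moved by exactly the offset, everything else intact
  expect_true(all(abs(d[changed] + 0.2) < 1e-12))
  expect_true(all(d[-changed] == 0))
})

test_that("trace noise matches the injected normal noise level", {
  p <- waveform_params(noise_sd = 0.05)
  p0 <- waveform_params(noise_sd = 0)
  set.seed(99)
  noisy <- synth_beat(p, "exercise")
  clean <- synth_beat(p0, "exercise")
  n <- length(noisy)
  # reference: the same normal draws from an independent re-run of the RNG
  set.seed(99)
  ref_noise <- rnorm(n, 0, 0.05)
  expect_equal(noisy - clean, ref_noise)
  # mean |noise| close to the half-normal mean 0.05 * sqrt(2/pi)
  expect_lt(abs(mean(abs(noisy - clean)) - 0.05 * sqrt(2 / pi)),
            3 * 0.05 / sqrt(n))
})

test_that("invalid waveform parameters are rejected", {
  expect_error(waveform_params(heart_rate_bpm = c(pretest = -5, exercise = 120,
                                                  recovery = 90)), "positive")
  expect_error(waveform_params(noise_sd = -1), "nonnegative")
  expect_error(waveform_params(sampling_rate = 0), "positive")
  p <- waveform_params(duration_s = 0.1)  # shorter than one beat
  expect_error(synth_beat(p, "pretest"), "beat period")
})

test_that("rendered pages have the requested resolution and structure", {
  rep <- tiny_report()
  expect_equal(dim(rep$pages$pretest), c(640, 1080))
  # blank traces give a horizontal line per lead tile plus grid pixels
  page <- render_state_page(matrix(0, 200, 12), "pretest")
  expect_equal(dim(page), c(640, 1080))
  expect_true(any(page == 220))   # grid present
  plot_region <- page[61:636, ]
  for (r in 0:5) {     # each tile row contains a horizontal run of trace
    tile <- plot_region[(r * 96 + 1):((r + 1) * 96), 1:540]
    rows_with_ink <- which(rowSums(tile == 0) > 0)
    expect_lte(length(rows_with_ink), 2)    # flat line (tile centre)
    expect_gt(max(rowSums(tile == 0)), 400) # long horizontal run
  }
  expect_error(render_state_page(matrix(0, 10, 5), "pretest"), "12")
})

test_that("binarization keeps trace pixels and the state keyword survives cropping out", {
  rep <- tiny_report()
  page <- rep$pages$exercise
  trace_px <- sum(page == 0)
  bin <- binarize(page, binarization_spec())
  expect_equal(sum(bin == 0), trace_px)   # every dark pixel survives
})

test_that("cohort label counts are exact and degenerate prevalence works", {
  co <- generate_cohort(cohort_config(n_patients = 416, prevalence = 192 / 416,
                                      seed = 1), traces = FALSE)
  expect_equal(sum(co$metadata$label == "CAD"), 192)
  expect_equal(sum(co$metadata$label == "non-CAD"), 224)

  co0 <- generate_cohort(cohort_config(n_patients = 10, prevalence = 0,
                                       seed = 1), traces = FALSE)
  expect_true(all(co0$metadata$label == "non-CAD"))
  offs <- vapply(co0$patients, function(p) max(abs(p$params$st_offset)),
                 numeric(1))
  expect_true(all(offs == 0))
})

test_that("age bins follow the configured multinomial proportions", {
  cfg <- cohort_config(n_patients = 1000, prevalence = 0.5, seed = 0)
  co <- generate_cohort(cfg, traces = FALSE)
  counts <- table(age_bin(co$metadata$age))
  p <- cfg$age_bin_probabilities
  expected <- 1000 * p
  sds <- sqrt(1000 * p * (1 - p))
  expect_true(all(abs(as.numeric(counts) - expected) <= 4 * sds))
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_patients = 3, prevalence = 0.5, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(patient_pages(a$patients[[2]], cfg),
                   patient_pages(b$patients[[2]], cfg))
})

test_that("class signal is purely inter-state in inter-state-only mode", {
  base_cfg <- cohort_config(n_patients = 2, prevalence = 0.5, seed = 5,
                            mode = "inter_state_only", noise_sd = 0)
  co <- generate_cohort(base_cfg)
  cad <- which(co$metadata$label == "CAD")[1]
  non <- which(co$metadata$label == "non-CAD")[1]
  # match every nuisance parameter; leave only the class effect
  p_cad <- co$patients[[cad]]$params
  p_non <- p_cad
  p_non$st_offset <- c(pretest = 0, exercise = 0, recovery = 0)
  pre_cad <- render_state_page(tetdia:::state_traces(p_cad, "pretest"), "pretest")
  pre_non <- render_state_page(tetdia:::state_traces(p_non, "pretest"), "pretest")
  ex_cad <- render_state_page(tetdia:::state_traces(p_cad, "exercise"), "exercise")
  ex_non <- render_state_page(tetdia:::state_traces(p_non, "exercise"), "exercise")
  expect_identical(as.numeric(pre_cad), as.numeric(pre_non))
  expect_false(identical(as.numeric(ex_cad), as.numeric(ex_non)))
})

test_that("invalid cohort configurations error", {
  expect_error(cohort_config(prevalence = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(n_patients = 1), "at least 2")
  expect_error(cohort_config(lead_rows = 5, lead_cols = 2), "12")
  expect_error(cohort_config(age_bin_probabilities = rep(0.25, 4)), "5 values")
})

test_that("write_cohort produces pages, sidecars and metadata on disk", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_patients = 2, prevalence = 0.5, seed = 2))
  write_cohort(co, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 6)
  expect_length(list.files(dir, pattern = "truth\\.json$"), 6)
  md <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(md), 2)
  expect_named(md, c("id", "label", "gender", "age"))
  # sidecar stub identifies states from disk
  pages <- render_report(file.path(dir))
  expect_error(identify_state_pages(pages[1:6], sidecar_text_extractor()), NA)
})
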