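#' Waveform parameters for one synthetic patient
#'
#' Describes the quasi-ECG trace model for all three TET states of one
#' patient.  The trace is a sum of a Gaussian P wave, a triangular QRS
#' complex, a piecewise-constant ST-segment level, and a Gaussian T wave,
#' repeated at the state's heart rate, plus white noise.  Amplitudes are in
#' trace units (nominally mV).
#'
#' @param heart_rate_bpm Named positive vector, one rate per state
#'   (`pretest`, `exercise`, `recovery`); exercise must exceed pretest.
#' @param amplitude_scale Positive length-12 vector, per-lead QRS scaling.
#' @param st_offset Named vector per state: the disease (CAD) effect on the
#'   ST-segment level; all zero for non-CAD patients.
#' @param st_baseline Single value: the patient's stable ST-level trait,
#'   applied identically in every state.
#' @param t_wave_scale Positive scalar scaling the T wave.
#' @param noise_sd Nonnegative noise standard deviation.
#' @param sampling_rate Samples per second.
#' @param duration_s Trace duration in seconds.
#' @return Object of class `"waveform_params"`.
#' @export
waveform_params <- function(heart_rate_bpm = c(pretest = 75, exercise = 140, recovery = 100),
                            amplitude_scale = rep(1, 12),
                            st_offset = c(pretest = 0, exercise = 0, recovery = 0),
                            st_baseline = 0,
                            t_wave_scale = 1,
                            noise_sd = 0,
                            sampling_rate = 250,
                            duration_s = 4) {
  stopifnot(length(heart_rate_bpm) == 3, length(st_offset) == 3,
            length(amplitude_scale) == 12)
  if (any(heart_rate_bpm <= 0)) stop("heart rates must be positive")
  if (heart_rate_bpm[["exercise"]] <= heart_rate_bpm[["pretest"]])
    stop("exercise heart rate must exceed the pretest rate")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (sampling_rate <= 0 || duration_s <= 0)
    stop("sampling rate and duration must be positive")
  structure(list(heart_rate_bpm = heart_rate_bpm,
                 amplitude_scale = amplitude_scale,
                 st_offset = st_offset, st_baseline = st_baseline,
                 t_wave_scale = t_wave_scale, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, duration_s = duration_s),
            class = "waveform_params")
}

# Beat phase windows (fractions of one beat period).
BEAT_PHASE <- list(p_center = 0.15, p_sd = 0.025,
                   qrs_center = 0.32, qrs_half = 0.035,
                   st_lo = 0.40, st_hi = 0.55,
                   t_center = 0.65, t_sd = 0.05)

# Noiseless single-beat shape evaluated at phase in [0,1); amplitude 1 QRS.
beat_shape <- function(phase, t_wave_scale = 1) {
  p <- BEAT_PHASE
  pw <- 0.15 * exp(-0.5 * ((phase - p$p_center) / p$p_sd)^2)
  qrs <- pmax(0, 1 - abs(phase - p$qrs_center) / p$qrs_half)
  tw <- 0.30 * t_wave_scale * exp(-0.5 * ((phase - p$t_center) / p$t_sd)^2)
  pw + qrs + tw
}

#' Synthesize a single-lead TET trace
#'
#' Generates the quasi-periodic trace for one lead in one state: P wave, QRS
#' spike, ST segment at level `st_baseline + st_offset[state]` over a fixed
#' phase window, T wave, plus `N(0, noise_sd)` noise drawn from the current
#' RNG state.
#'
#' @param params A [waveform_params()].
#' @param state One of `"pretest"`, `"exercise"`, `"recovery"`.
#' @param lead Lead index 1--12 (selects the amplitude scale).
#' @return Numeric vector of `duration_s * sampling_rate` samples.
#' @export
synth_beat <- function(params, state = "pretest", lead = 1L) {
  stopifnot(inherits(params, "waveform_params"))
  state <- match.arg(state, TET_STATES)
  n <- round(params$duration_s * params$sampling_rate)
  period <- params$sampling_rate * 60 / params$heart_rate_bpm[[state]]
  if (n < period) stop("duration must cover at least one beat period")
  t <- 0:(n - 1)
  phase <- (t %% period) / period
  st_level <- params$st_baseline + params$st_offset[[state]]
  polarity <- if (lead == 4L) -1 else 1   # aVR is conventionally inverted
  tr <- polarity * params$amplitude_scale[[lead]] *
    beat_shape(phase, params$t_wave_scale) +
    st_level * (phase >= BEAT_PHASE$st_lo & phase < BEAT_PHASE$st_hi)
  if (params$noise_sd > 0) tr <- tr + rnorm(n, 0, params$noise_sd)
  tr
}

# All 12 leads for one state: n_samples x 12 matrix.
state_traces <- function(params, state) {
  vapply(1:12, function(g) synth_beat(params, state, g),
         numeric(round(params$duration_s * params$sampling_rate)))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the demographic structure of a published clinical TET cohort:
#' 416 patients, 192 with obstructive CAD, gender split 299 male / 117
#' female, and the printed age-bin counts 16/39/119/118/4 over
#' `{<=40, (40,50], (50,60], (60,70], >70}` (normalized to proportions).
#'
#' @param n_patients Number of patients (>= 2).
#' @param prevalence Fraction of CAD patients in `[0, 1]`.
#' @param seed Integer; patient `i` uses the derived stream `seed + i`.
#' @param gender_proportions Named pair summing to 1.
#' @param age_bin_probabilities Five probabilities summing to 1.
#' @param page_size `c(width, height)` pixels of a rendered page.
#' @param lead_rows,lead_cols Lead grid of the rendered page, rows*cols == 12.
#' @param mode `"full"` (CAD shows a small resting ST depression in pretest
#'   plus the exercise-induced effect) or `"inter_state_only"` (pretest
#'   carries no class effect at all, so the class signal is purely the
#'   change between states).
#' @param st_effect Exercise-state ST depression for CAD patients (trace
#'   units; negative).  Recovery shows half the effect, pretest a third in
#'   `"full"` mode and zero in `"inter_state_only"` mode.
#' @param st_trait_sd Between-patient sd of the stable ST-level trait.
#' @param noise_sd Trace noise sd.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 416,
                          prevalence = 192 / 416,
                          seed = 0L,
                          gender_proportions = c(male = 299, female = 117) / 416,
                          age_bin_probabilities = c(16, 39, 119, 118, 4) / 296,
                          page_size = c(1080, 640),
                          lead_rows = 6L, lead_cols = 2L,
                          mode = c("full", "inter_state_only"),
                          st_effect = -0.15,
                          st_trait_sd = 0.20,
                          noise_sd = 0.02) {
  mode <- match.arg(mode)
  if (n_patients < 2) stop("n_patients must be at least 2")
  if (prevalence < 0 || prevalence > 1) stop("prevalence must lie in [0, 1]")
  if (abs(sum(gender_proportions) - 1) > 1e-9)
    stop("gender proportions must sum to 1")
  if (length(age_bin_probabilities) != 5 ||
      abs(sum(age_bin_probabilities) - 1) > 1e-9)
    stop("age bin probabilities must be 5 values summing to 1")
  if (lead_rows * lead_cols != 12) stop("lead grid must have rows*cols == 12")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 seed = as.integer(seed),
                 gender_proportions = gender_proportions,
                 age_bin_probabilities = age_bin_probabilities,
                 page_size = page_size,
                 lead_rows = as.integer(lead_rows),
                 lead_cols = as.integer(lead_cols),
                 mode = mode, st_effect = st_effect,
                 st_trait_sd = st_trait_sd, noise_sd = noise_sd),
            class = "cohort_config")
}

AGE_BIN_LABELS <- c("<=40", "(40,50]", "(50,60]", "(60,70]", ">70")
AGE_BIN_BREAKS <- c(-Inf, 40, 50, 60, 70, Inf)

# Per-state CAD effect sizes under a config.
class_effect <- function(cfg) {
  e <- cfg$st_effect
  pre <- if (cfg$mode == "inter_state_only") 0 else e / 3
  c(pretest = pre, exercise = e, recovery = e / 2)
}

#' Generate a synthetic TET cohort
#'
#' Draws exactly `round(n_patients * prevalence)` CAD patients (positions
#' randomized), samples demographics from the configured proportions, and
#' creates per-state waveform parameters and 12-lead traces for every
#' patient.  Each patient uses its own RNG stream derived as `seed + index`,
#' so generation is reproducible patient by patient.
#'
#' @param cfg A [cohort_config()].
#' @param traces If `TRUE` (default) the per-state 12-lead traces are
#'   computed and stored on each patient's pages; pass `FALSE` for a
#'   metadata-only cohort.
#' @return Object of class `"tet_cohort"`: list with `patients` (each with
#'   id, label, gender, age, `params`, and three `pages` holding state +
#'   traces), `metadata` (data.frame id, label, gender, age), and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), traces = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_patients
  n_cad <- round(n * cfg$prevalence)
  set.seed(cfg$seed)
  labels <- rep("non-CAD", n)
  labels[sample.int(n, n_cad)] <- "CAD"
  eff <- class_effect(cfg)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(cfg$seed + i)
    gender <- sample(names(cfg$gender_proportions), 1,
                     prob = cfg$gender_proportions)
    bin <- sample.int(5, 1, prob = cfg$age_bin_probabilities)
    age <- switch(bin, sample(25:40, 1), sample(41:50, 1), sample(51:60, 1),
                  sample(61:70, 1), sample(71:85, 1))
    hr_pre <- rnorm(1, 75, 8)
    hr_ex <- max(rnorm(1, 140, 15), hr_pre + 20)
    hr_rec <- max(rnorm(1, 100, 10), 40)
    is_cad <- labels[i] == "CAD"
    params <- waveform_params(
      heart_rate_bpm = c(pretest = max(hr_pre, 40), exercise = hr_ex,
                         recovery = hr_rec),
      amplitude_scale = exp(rnorm(12, 0, 0.15)),
      st_offset = if (is_cad) eff else c(pretest = 0, exercise = 0, recovery = 0),
      st_baseline = rnorm(1, 0, cfg$st_trait_sd),
      t_wave_scale = max(rnorm(1, 1, 0.1), 0.3),
      noise_sd = cfg$noise_sd)
    pages <- lapply(TET_STATES, function(s) {
      list(state = s,
           traces = if (traces) state_traces(params, s) else NULL)
    })
    names(pages) <- TET_STATES
    patients[[i]] <- structure(
      list(patient_id = sprintf("P%04d", i), label = labels[i],
           gender = gender, age = age, params = params, pages = pages),
      class = "tet_patient")
  }
  metadata <- data.frame(
    id = vapply(patients, `[[`, character(1), "patient_id"),
    label = labels,
    gender = vapply(patients, `[[`, character(1), "gender"),
    age = vapply(patients, `[[`, integer(1), "age"),
    stringsAsFactors = FALSE)
  structure(list(patients = patients, metadata = metadata, config = cfg),
            class = "tet_cohort")
}

#' @export
print.tet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TET cohort: %d patients (%d CAD / %d non-CAD), mode '%s'\n",
              nrow(x$metadata), sum(x$metadata$label == "CAD"),
              sum(x$metadata$label == "non-CAD"), x$config$mode))
  invisible(x)
}

#' Render one state page of a report
#'
#' Draws a light grid background, the 12 lead traces as dark polylines in a
#' `lead_rows` x `lead_cols` tile grid, and the state keyword stamped as
#' bitmap text in the banner strip.  The true state travels with the image
#' as the `truth_state` attribute (the machine-readable sidecar).
#'
#' @param traces `n_samples` x 12 matrix, one column per lead in standard
#'   lead order.
#' @param state The page's TET state.
#' @param page_size `c(width, height)` pixels.
#' @param lead_rows,lead_cols Lead tile grid (rows*cols must be 12).
#' @param gain Vertical scale in pixels per trace unit.
#' @param banner_height Height of the text banner strip in pixels.
#' @return `height` x `width` grayscale matrix (255 background, 220 grid,
#'   0 trace/text) with attribute `truth_state`.
#' @export
render_state_page <- function(traces, state, page_size = c(1080, 640),
                              lead_rows = 6L, lead_cols = 2L, gain = 30,
                              banner_height = 60L) {
  if (is.null(dim(traces)) || ncol(traces) != 12)
    stop("traces must be a matrix with exactly 12 columns")
  state <- match.arg(state, TET_STATES)
  W <- page_size[1]; H <- page_size[2]
  if (W <= 0 || H <= 0) stop("page size must be positive")
  page <- matrix(255, H, W)
  tile_h <- (H - banner_height) %/% lead_rows
  tile_w <- W %/% lead_cols
  plot_rows <- (banner_height + 1):(banner_height + lead_rows * tile_h)
  plot_cols <- seq_len(lead_cols * tile_w)
  # grid every 20 px within the plot region
  page[plot_rows[seq(1, length(plot_rows), by = 20)], plot_cols] <- 220
  page[plot_rows, plot_cols[seq(1, length(plot_cols), by = 20)]] <- 220
  margin <- 10L
  for (g in 1:12) {
    r <- (g - 1) %/% lead_cols; cc <- (g - 1) %% lead_cols
    top <- banner_height + r * tile_h
    left <- cc * tile_w
    inner_w <- tile_w - 2L * margin
    y0 <- top + tile_h / 2
    # one trace sample per pixel column via linear interpolation
    v <- stats::approx(seq_len(nrow(traces)), traces[, g],
                       xout = seq(1, nrow(traces), length.out = inner_w))$y
    y <- round(y0 - gain * v)
    y <- pmin(pmax(y, top + 1L), top + tile_h)
    for (k in seq_len(inner_w)) {
      x <- left + margin + k
      rows <- if (k == 1) y[k] else min(y[k - 1], y[k]):max(y[k - 1], y[k])
      page[rows, x] <- 0
    }
  }
  page <- stamp_text(page, state, top = 16L, left = 40L, scale = 4L, value = 0)
  attr(page, "truth_state") <- state
  page
}

#' Render the three report pages of a synthetic patient
#'
#' @param patient A `"tet_patient"` from [generate_cohort()].
#' @param cfg The cohort's [cohort_config()] (controls page geometry).
#' @return Named list of three page matrices (`pretest`, `exercise`,
#'   `recovery`), each carrying its `truth_state` attribute.
#' @export
patient_pages <- function(patient, cfg = cohort_config()) {
  stopifnot(inherits(patient, "tet_patient"))
  out <- lapply(TET_STATES, function(s) {
    tr <- patient$pages[[s]]$traces
    if (is.null(tr)) tr <- state_traces(patient$params, s)
    render_state_page(tr, s, page_size = cfg$page_size,
                      lead_rows = cfg$lead_rows, lead_cols = cfg$lead_cols)
  })
  names(out) <- TET_STATES
  out
}

#' Write a cohort to disk as PNG pages plus metadata
#'
#' Creates `<id>_<state>.png` for every patient page, a `metadata.csv` with
#' columns id,label,gender,age, and a `<id>_<state>.truth.json` sidecar per
#' page recording the true state.
#'
#' @param cohort A `"tet_cohort"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    pages <- patient_pages(p, cohort$config)
    for (s in TET_STATES) {
      stem <- file.path(dir, paste0(p$patient_id, "_", s))
      png::writePNG(pages[[s]] / 255, paste0(stem, ".png"))
      jsonlite::write_json(list(patient_id = p$patient_id, state = s,
                                file = paste0(stem, ".png")),
                           paste0(stem, ".truth.json"), auto_unbox = TRUE)
    }
  }
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
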