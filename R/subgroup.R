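#' Assign ages to the report's age bins
#'
#' Bins are closed on the right: `<=40`, `(40,50]`, `(50,60]`, `(60,70]`,
#' `>70`.
#'
#' @param age Integer vector of ages in years.
#' @return Factor with the five bin labels.
#' @export
age_bin <- function(age) {
  cut(age, breaks = AGE_BIN_BREAKS, labels = AGE_BIN_LABELS, right = TRUE)
}

#' Per-gender and per-age-bin diagnostic metrics
#'
#' Stratifies the samples by gender and by age bin and computes the five
#' diagnostic metrics within each group.  Groups with no samples are kept in
#' the table with `n = 0` and `NA` metrics.
#'
#' @param predictions Predicted labels.
#' @param labels True labels.
#' @param metadata Data frame with one row per sample and columns `gender`
#'   (`"male"`/`"female"`) and `age`.
#' @return Data frame with columns `group`, `level`, `n` and the five
#'   metrics (fractions in `[0, 1]`).
#' @export
subgroup_report <- function(predictions, labels, metadata) {
  n <- length(predictions)
  if (nrow(metadata) != n)
    stop("metadata must have one row per sample (got ", nrow(metadata),
         " rows for ", n, " samples)")
  if (anyNA(metadata$gender) || anyNA(metadata$age)) {
    bad <- which(is.na(metadata$gender) | is.na(metadata$age))
    stop("missing metadata for sample(s): ", paste(head(bad, 5), collapse = ", "))
  }
  strata <- list(gender = factor(metadata$gender, c("male", "female")),
                 age = age_bin(metadata$age))
  rows <- list()
  for (grp in names(strata)) {
    f <- strata[[grp]]
    for (lev in levels(f)) {
      sel <- which(f == lev)
      m <- if (length(sel))
        tet_metrics(confusion(predictions[sel], labels[sel]))
      else
        list(accuracy = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_, precision = NA_real_, npv = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, level = lev, n = length(sel),
        accuracy = m$accuracy, sensitivity = m$sensitivity,
        specificity = m$specificity, precision = m$precision, npv = m$npv)
    }
  }
  do.call(rbind, rows)
}

#' Stratified train/test split
#'
#' Splits sample indices by label with the study's default training
#' fraction 353/416, seed-controlled.
#'
#' @param labels Label vector.
#' @param train_frac Fraction of each class assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(labels, train_frac = 353 / 416, seed = 0L) {
  labels <- as.character(labels)
  set.seed(seed)
  train <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    k <- round(length(idx) * train_frac)
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Sensitivity of diagnostic accuracy to the inter-state group count
#'
#' Trains one model per requested group count `g` with a shared seed and
#' reports the test accuracy of each, after checking that every channel
#' count in the architecture (36, 72, 144, 288, 576) is divisible by each
#' `g`.
#'
#' @param x,y Samples and labels as for [tetdianet()].
#' @param g_values Integer group counts (the published sweep is
#'   `c(4, 6, 9, 12, 18)`).
#' @param net Base [network_config()]; its `groups` field is replaced per
#'   run.
#' @param control A [train_control()].
#' @param split A [split_cohort()] result; default splits `y` with seed
#'   `seed`.
#' @param seed Shared training seed.
#' @return Data frame with columns `g` and `accuracy`.
#' @export
g_sensitivity <- function(x, y, g_values = c(4, 6, 9, 12, 18),
                          net = network_config(input_size = 112L),
                          control = desk_control(), split = NULL, seed = 0L) {
  channel_counts <- unique(c(net$in_channels,
                             vapply(net$blocks, `[[`, integer(1), "out_channels")))
  for (g in g_values)
    if (any(channel_counts %% g != 0))
      stop(sprintf("g = %d does not divide every channel count (%s)",
                   g, paste(channel_counts, collapse = ", ")))
  if (is.null(split)) split <- split_cohort(y, seed = seed)
  acc <- vapply(g_values, function(g) {
    cfg <- network_config(input_size = net$input_size,
                          in_channels = net$in_channels, groups = as.integer(g),
                          inter_state = net$inter_state, hidden = net$hidden,
                          n_classes = net$n_classes)
    fit <- tetdianet(x[split$train], y[split$train], net = cfg,
                     control = control, seed = seed)
    pred <- predict(fit, x[split$test], type = "class")
    tet_metrics(confusion(pred, y[split$test]))$accuracy
  }, numeric(1))
  data.frame(g = g_values, accuracy = acc)
}
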