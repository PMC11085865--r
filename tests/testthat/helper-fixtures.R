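# Shared fixtures, generated in code.

# A small rendered report (three state pages) for one synthetic patient.
tiny_report <- function(seed = 11, mode = "full", page_size = c(1080, 640)) {
  cfg <- cohort_config(n_patients = 2, prevalence = 0.5, seed = seed,
                       mode = mode, page_size = page_size)
  co <- generate_cohort(cfg)
  list(pages = patient_pages(co$patients[[1]], cfg), cohort = co, cfg = cfg)
}

# Direct (four-nested-loop) depthwise convolution, the independent oracle
# for the intra-state operator: zero padding, one filter per channel.
dw_conv_oracle <- function(x, w, stride = 1L, pad = NULL) {
  d <- dim(x); dk <- dim(w)[1]
  if (is.null(pad)) pad <- dk %/% 2L
  Ho <- (d[1] + 2 * pad - dk) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - dk) %/% stride + 1L
  out <- array(0, dim = c(Ho, Wo, d[3]))
  for (m in seq_len(d[3]))
    for (ko in seq_len(Ho))
      for (lo in seq_len(Wo))
        for (i in seq_len(dk))
          for (j in seq_len(dk)) {
            h <- (ko - 1) * stride - pad + i
            wcol <- (lo - 1) * stride - pad + j
            if (h >= 1 && h <= d[1] && wcol >= 1 && wcol <= d[2])
              out[ko, lo, m] <- out[ko, lo, m] + w[i, j, m] * x[h, wcol, m]
          }
  out
}

# Direct per-pixel per-group matrix product, the oracle for the inter-state
# operator.
gconv_oracle <- function(x, w) {
  d <- dim(x); g <- dim(w)[3]
  ci <- d[3] %/% g; co <- dim(w)[2]
  out <- array(0, dim = c(d[1], d[2], co * g))
  for (k in seq_len(d[1]))
    for (l in seq_len(d[2]))
      for (gr in seq_len(g))
        for (mo in seq_len(co))
          for (mi in seq_len(ci))
            out[k, l, (gr - 1) * co + mo] <- out[k, l, (gr - 1) * co + mo] +
              w[mi, mo, gr] * x[k, l, (gr - 1) * ci + mi]
  out
}
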