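# Shared fixture builders. Everything is generated in code at test time.

# Render a slide whose pixels come from known stain ODs (no noise, continuous
# intensities), for unmixing round-trip tests.
slide_from_od <- function(h_od, e_od, resolution = 500) {
  sv <- default_stain_vectors()
  nr <- nrow(h_od); nc <- ncol(h_od)
  px <- array(0, c(nr, nc, 3))
  for (ch in 1:3)
    px[, , ch] <- 255 * 10^(-(h_od * sv[ch, 1] + e_od * sv[ch, 2]))
  slide_image(px, resolution)
}

# OD that renders a single-stain image with a given HSV saturation; inverts
# s = 1 - 10^(-od * (max(v) - min(v))).
od_for_saturation <- function(s, stain = c("hematoxylin", "eosin")) {
  stain <- match.arg(stain)
  v <- default_stain_vectors()[, stain]
  if (s <= 0) return(0)
  -log10(1 - s) / (max(v) - min(v))
}

# A binary stain map built directly from a label matrix.
stain_map_from_labels <- function(lab) {
  structure(list(labels = lab), class = "binary_stain_map")
}

# Minimal scatter_model stub: enough for predict() / classification tests.
stub_model <- function(family, params, property_name = NA, fraction_name = NA) {
  p <- length(params)
  structure(
    list(family = family, property_name = property_name,
         fraction_name = fraction_name, params = params,
         param_cov = matrix(0, p, p), rmse = 0, r2_adj = 1, sse = 0,
         n_fit = 20L, x_range = c(-Inf, Inf)),
    class = "scatter_model")
}

# Nine stub models that return a constant per fraction.
constant_models <- function(stroma, epithelium, adipose) {
  const_logistic <- function(v) {
    # a near-flat logistic: w huge, center placed so f(x) ~ v for any small x
    stub_model("logistic2", c(c = -1e6 * log(1 / v - 1), w = 1e6))
  }
  out <- list()
  for (fr in c("stroma", "epithelium", "adipose")) {
    v <- switch(fr, stroma = stroma, epithelium = epithelium,
                adipose = adipose)
    out[[fr]] <- list()
    for (pr in c("mus_prime", "gamma", "b_power"))
      out[[fr]][[pr]] <- const_logistic(v)
  }
  out
}

# Small latent-mode config for fast property tests.
small_cohort_config <- function(seed, ...) {
  cohort_config(n_invasive = 5, n_fibroglandular = 8, n_fat = 3,
                pixels_per_specimen = c(100, 400), seed = seed, ...)
}

zero_noise <- c(mus_prime = 0, gamma = 0, b_power = 0)

# Run a cli_main call while swallowing the usage text it prints.
capture_usage <- function(expr) {
  out <- NULL
  utils::capture.output(out <- expr)
  out
}
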