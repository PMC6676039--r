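# Synthetic data emulating the study design: H&E-like slide renderings with
# known stain composition, and a specimen cohort whose stroma/adipose fractions
# follow logistic curves and epithelium a peaked Gaussian versus each
# light-scattering property, with the 10/16/5 invasive/fibroglandular/fat
# class structure of the emulated 31-specimen cohort.

PATHOLOGY_LEVELS <- c("invasive", "fibroglandular", "fat")

# Restore the caller's RNG state when the generator returns.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic cohort configuration
#'
#' All generator constants in one place. A single latent morphology axis `m`
#' in `[0, 1]` (fat near 0, invasive near 0.5, fibroglandular near 1) drives
#' both the tissue fractions and the three optical properties, reproducing the
#' cross-sectional curve shapes the analysis assumes: adipose
#' `= logistic(m; c = 0.25, w = 0.06)` (decreasing in m), epithelium
#' `= (1 - adipose) * exp(-(m - 0.5)^2 / (2 * 0.12^2))` (peaked), stroma the
#' remainder. Properties are monotone affine maps of `m` plus Gaussian noise:
#' `mu_s' = 0.5 + 1.5 m`, `gamma = 1.9 - 0.5 m`, `B = 0.2 + 1.3 m`.
#'
#' @param n_invasive,n_fibroglandular,n_fat Specimen counts (defaults 10, 16,
#'   5, the emulated cohort's class sizes).
#' @param pixels_per_specimen Range of per-specimen pixel counts (default
#'   200-3000).
#' @param noise_sd Named per-property Gaussian pixel noise SDs.
#' @param fraction_noise_sd SD of additive noise on observed specimen
#'   fractions (clipped to `[0, 1]` and renormalized to the simplex).
#' @param m_jitter_sd SD of the spatially smoothed per-pixel jitter on `m`.
#' @param blur_mm Gaussian smoothing scale of the pixel jitter, mm (mimics the
#'   roughly 1-2 mm spatial resolution of scattering maps); default 1.
#' @param pixel_size Optical map pixel side, mm; default 0.5.
#' @param latent_beta Per-class `c(shape1, shape2)` of the Beta distribution
#'   of the specimen latent state `m`.
#' @param property_maps Per-property `c(intercept, slope)` of the affine map
#'   from `m`.
#' @param fraction_source `"latent"` (default; fractions from the latent
#'   curves above, summing to 1) or `"curves"` (fractions drawn exactly from
#'   fixed logistic/Gaussian reference curves of `m`, for closed-loop model
#'   recovery; they need not sum to 1).
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_invasive = 10, n_fibroglandular = 16, n_fat = 5,
                          pixels_per_specimen = c(200, 3000),
                          noise_sd = c(mus_prime = 0.05, gamma = 0.03,
                                       b_power = 0.05),
                          fraction_noise_sd = 0.05,
                          m_jitter_sd = 0.05, blur_mm = 1, pixel_size = 0.5,
                          latent_beta = list(fat = c(2, 10),
                                             invasive = c(20, 20),
                                             fibroglandular = c(10, 2)),
                          property_maps = list(mus_prime = c(0.5, 1.5),
                                               gamma = c(1.9, -0.5),
                                               b_power = c(0.2, 1.3)),
                          fraction_source = c("latent", "curves"),
                          seed = 1L) {
  fraction_source <- match.arg(fraction_source)
  if (any(c(n_invasive, n_fibroglandular, n_fat) < 0))
    stop("specimen counts must be nonnegative")
  if (any(noise_sd < 0) || fraction_noise_sd < 0 || m_jitter_sd < 0)
    stop("noise scales must be nonnegative")
  structure(
    list(n_invasive = n_invasive, n_fibroglandular = n_fibroglandular,
         n_fat = n_fat, pixels_per_specimen = pixels_per_specimen,
         noise_sd = noise_sd, fraction_noise_sd = fraction_noise_sd,
         m_jitter_sd = m_jitter_sd, blur_mm = blur_mm,
         pixel_size = pixel_size, latent_beta = latent_beta,
         property_maps = property_maps, fraction_source = fraction_source,
         seed = as.integer(seed)),
    class = "cohort_config")
}

# Latent-axis generator curves. Adipose decreases in m, epithelium peaks at
# m = 0.5 under the (1 - adipose) envelope, stroma takes the remainder; the
# three always sum to 1 and stroma is never negative.
latent_fractions <- function(m) {
  adipose <- logistic2(m, c = 0.25, w = 0.06)
  epithelium <- (1 - adipose) * exp(-(m - 0.5)^2 / (2 * 0.12^2))
  stroma <- 1 - adipose - epithelium
  if (any(stroma < -1e-12)) stop("inconsistent generator curves")
  cbind(epithelium = epithelium, stroma = pmax(stroma, 0), adipose = adipose)
}

# Reference curves in the fitted families, used by fraction_source = "curves".
# Exact logistic2/gaussian3 functions of m, hence of every affine property.
curve_fractions <- function(m) {
  cbind(epithelium = gaussian3(m, a = 0.8, c = 0.5, w = 0.12),
        stroma = logistic2(m, c = 0.65, w = -0.10),
        adipose = logistic2(m, c = 0.25, w = 0.06))
}

# Separable Gaussian blur with reflected edges; sigma in pixels.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  blur1d <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - rev(seq_len(half)))
    idx <- pmin(pmax(idx, 1L), n)
    as.numeric(stats::filter(v[idx], k, sides = 2))[half + seq_len(n)]
  }
  mat <- apply(mat, 2, blur1d)
  t(apply(mat, 1, blur1d))
}

#' Generate a synthetic specimen cohort
#'
#' Draws, per specimen: a latent state `m` from its class Beta distribution; a
#' per-pixel optical property map (affine maps of a spatially smoothed,
#' jittered `m` plus Gaussian noise); and observed specimen fractions (true
#' fractions plus clipped, renormalized noise). ROI summaries use the whole
#' map. The same config (including its seed) always reproduces the same
#' cohort.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (specimen table: id, class, subtype, per-property
#'   and per-fraction ROI mean/sd), `truth` (latent `m`, true fractions, true
#'   class), and `maps` (list of [optical_property_map()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    classes <- rep(PATHOLOGY_LEVELS,
                   c(config$n_invasive, config$n_fibroglandular, config$n_fat))
    n <- length(classes)
    if (n == 0) stop("empty cohort")
    ids <- sprintf("S%02d", seq_len(n))
    m_spec <- vapply(classes, function(cl) {
      ab <- config$latent_beta[[if (cl == "invasive") "invasive"
                                else if (cl == "fat") "fat"
                                else "fibroglandular"]]
      stats::rbeta(1, ab[1], ab[2])
    }, numeric(1))

    frac_fun <- switch(config$fraction_source,
                       latent = latent_fractions, curves = curve_fractions)
    true_frac <- frac_fun(m_spec)

    # observed specimen fractions: additive noise on the simplex
    obs_frac <- true_frac +
      matrix(stats::rnorm(3 * n, sd = config$fraction_noise_sd), n, 3)
    obs_frac <- pmin(pmax(obs_frac, 0), 1)
    if (config$fraction_source == "latent") {
      s <- rowSums(obs_frac)
      s[s == 0] <- 1
      obs_frac <- obs_frac / s
    }
    colnames(obs_frac) <- colnames(true_frac)

    maps <- vector("list", n)
    prop_stats <- matrix(NA_real_, n, 6,
                         dimnames = list(NULL, paste0(
                           rep(PROPERTIES, each = 2), c("_mean", "_sd"))))
    frac_sd <- matrix(0, n, 3,
                      dimnames = list(NULL, colnames(true_frac)))
    for (i in seq_len(n)) {
      npix <- stats::runif(1, config$pixels_per_specimen[1],
                           config$pixels_per_specimen[2])
      side <- max(2L, round(sqrt(npix)))
      jit <- matrix(stats::rnorm(side^2, sd = config$m_jitter_sd), side, side)
      jit <- gaussian_blur(jit, config$blur_mm / config$pixel_size)
      m_pix <- m_spec[i] + jit
      props <- list()
      for (pr in PROPERTIES) {
        ab <- config$property_maps[[pr]]
        props[[pr]] <- ab[1] + ab[2] * m_pix +
          matrix(stats::rnorm(side^2, sd = config$noise_sd[[pr]]), side, side)
      }
      props$mus_prime <- pmax(props$mus_prime, 0.01)
      maps[[i]] <- optical_property_map(
        props$mus_prime, props$gamma, props$b_power,
        pixel_size = config$pixel_size, specimen_id = ids[i])
      for (pr in PROPERTIES) {
        prop_stats[i, paste0(pr, "_mean")] <- mean(props[[pr]])
        prop_stats[i, paste0(pr, "_sd")] <- stats::sd(props[[pr]])
      }
      pix_frac <- frac_fun(as.numeric(m_pix))
      frac_sd[i, ] <- apply(pix_frac, 2, stats::sd)
    }

    cohort <- data.frame(
      specimen_id = ids, class = classes,
      subtype = classes, stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(prop_stats))
    for (fr in colnames(obs_frac)) {
      cohort[[paste0(fr, "_mean")]] <- obs_frac[, fr]
      cohort[[paste0(fr, "_sd")]] <- frac_sd[, fr]
    }
    # the ground-truth class follows the dominant morphology of the true
    # fractions (it coincides with the pathology stratum except for rare
    # boundary draws of m)
    truth <- data.frame(
      specimen_id = ids, class = classes, m = m_spec,
      true_epithelium = true_frac[, "epithelium"],
      true_stroma = true_frac[, "stroma"],
      true_adipose = true_frac[, "adipose"],
      true_class = classify_fractions(true_frac[, "epithelium"],
                                      true_frac[, "stroma"],
                                      true_frac[, "adipose"]),
      stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth, maps = maps, config = config)
  })
}

# Per-tissue mean stain optical densities for the slide renderer.
HNE_TISSUE_OD <- list(
  epithelial = c(hematoxylin = 0.60, eosin = 0.05),
  stromal    = c(hematoxylin = 0.05, eosin = 0.50),
  adipose    = c(hematoxylin = 0.01, eosin = 0.01))

#' Render a synthetic H&E slide with known composition
#'
#' Paints tissue regions (rectangles/ellipses, last drawn wins) onto an
#' adipose (near-white) canvas, assigns each tissue its characteristic
#' hematoxylin/eosin optical densities plus optional Gaussian OD noise, and
#' renders `RGB = 255 * 10^(-sum(OD * stain_vector))`. Returns the image and
#' the true per-pixel tissue label for closed-loop segmentation tests.
#'
#' @param region_layout List of regions, each a list with `shape` (`"rect"`:
#'   fields `row0, col0, row1, col1`; `"ellipse"`: `row, col, r_row, r_col`),
#'   and `tissue` in `{epithelial, stromal, adipose}`. Coordinates in pixels.
#' @param canvas `c(rows, cols)` in pixels; default 200 x 200.
#' @param resolution Pixels per mm; default 500.
#' @param noise_sd SD of per-pixel OD noise; default 0.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param specimen_id Identifier for the resulting [slide_image()].
#' @return List with `image` (a `slide_image`) and `labels` (character matrix
#'   of true tissue types).
#' @export
generate_hne_image <- function(region_layout, canvas = c(200, 200),
                               resolution = 500, noise_sd = 0, seed = 1L,
                               specimen_id = "synthetic") {
  nr <- canvas[1]; nc <- canvas[2]
  lab <- matrix("adipose", nr, nc)
  rowi <- matrix(seq_len(nr), nr, nc)
  coli <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (reg in region_layout) {
    if (!reg$tissue %in% names(HNE_TISSUE_OD))
      stop("unknown tissue type: ", reg$tissue)
    inside <- switch(reg$shape,
      rect = rowi >= reg$row0 & rowi <= reg$row1 &
             coli >= reg$col0 & coli <= reg$col1,
      ellipse = ((rowi - reg$row) / reg$r_row)^2 +
                ((coli - reg$col) / reg$r_col)^2 <= 1,
      stop("unknown shape: ", reg$shape))
    if (!any(inside)) stop("region outside canvas")
    lab[inside] <- reg$tissue
  }
  h_map <- vapply(HNE_TISSUE_OD, `[[`, numeric(1), "hematoxylin")
  e_map <- vapply(HNE_TISSUE_OD, `[[`, numeric(1), "eosin")
  with_seed(seed, {
    h_od <- matrix(h_map[lab], nr, nc)
    e_od <- matrix(e_map[lab], nr, nc)
    if (noise_sd > 0) {
      h_od <- pmax(0, h_od + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc))
      e_od <- pmax(0, e_od + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc))
    }
    sv <- default_stain_vectors()
    px <- array(0, c(nr, nc, 3))
    for (ch in 1:3)
      px[, , ch] <- 255 * 10^(-(h_od * sv[ch, 1] + e_od * sv[ch, 2]))
    list(image = slide_image(px, resolution, specimen_id), labels = lab)
  })
}

#' Write the deterministic fixture suite
#'
#' Writes a small, reproducible set of synthetic inputs for tests and
#' documentation: three single-tissue slides, one heterogeneous slide (a
#' malignant lesion embedded in fat with a stromal band), their true label
#' maps, and one default synthetic cohort. Everything regenerates
#' byte-identically from the same seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; default 7.
#' @return Invisibly, the vector of files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 7L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(f) files <<- c(files, f)

  pure <- list(epithelial = "slide_epithelial", stromal = "slide_stromal",
               adipose = "slide_adipose")
  for (tissue in names(pure)) {
    # a 10-px unstained margin around the section acts as the white
    # reference for white balancing, as on a real scanned slide
    g <- generate_hne_image(
      list(list(shape = "rect", row0 = 11, col0 = 11, row1 = 110, col1 = 110,
                tissue = tissue)),
      canvas = c(120, 120), resolution = 500, noise_sd = 0.02, seed = seed,
      specimen_id = pure[[tissue]])
    f <- file.path(out_dir, paste0(pure[[tissue]], ".ppm"))
    write_ppm(g$image$pixels, f)
    put(f)
    f <- file.path(out_dir, paste0(pure[[tissue]], "_labels.pgm"))
    write_label_pgm(g$labels, f,
                    levels = c("adipose", "epithelial", "stromal"))
    put(f)
  }

  het <- generate_hne_image(
    list(list(shape = "rect", row0 = 1, col0 = 120, row1 = 200, col1 = 200,
              tissue = "stromal"),
         list(shape = "ellipse", row = 100, col = 70, r_row = 45, r_col = 40,
              tissue = "epithelial")),
    canvas = c(200, 200), resolution = 500, noise_sd = 0.02, seed = seed + 1L,
    specimen_id = "slide_heterogeneous")
  f <- file.path(out_dir, "slide_heterogeneous.ppm")
  write_ppm(het$image$pixels, f); put(f)
  f <- file.path(out_dir, "slide_heterogeneous_labels.pgm")
  write_label_pgm(het$labels, f,
                  levels = c("adipose", "epithelial", "stromal"))
  put(f)

  gen <- generate_cohort(cohort_config(seed = seed))
  f <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(gen$cohort, f); put(f)
  f <- file.path(out_dir, "truth.csv")
  utils::write.csv(gen$truth, f, row.names = FALSE); put(f)

  invisible(files)
}
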