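# Quantitative digital histology: white balance, stain unmixing, binary stain
# labelling, and voxelized volume fractions for H&E slides of breast tissue.

STAIN_LEVELS <- c("HEMATOXYLIN", "EOSIN", "NO_STAIN")

#' Construct a digitized slide image
#'
#' An 8-bit RGB image of an H&E-stained histology slide, digitized at a known
#' spatial resolution (typically 500 or 1000 pixels per mm).
#'
#' @param pixels Numeric array `rows x cols x 3`, channel values in `[0, 255]`.
#' @param resolution Scan resolution in pixels per mm (> 0).
#' @param specimen_id Identifier string.
#' @return A `slide_image` object.
#' @export
slide_image <- function(pixels, resolution, specimen_id = "unknown") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be a rows x cols x 3 array")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number (pixels per mm)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must be finite and in [0, 255]")
  structure(
    list(pixels = pixels, resolution = resolution,
         specimen_id = as.character(specimen_id)),
    class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("slide_image '%s': %d x %d px, %g px/mm\n",
              x$specimen_id, d[1], d[2], x$resolution))
  invisible(x)
}

#' White-balance a slide image
#'
#' Estimates a per-channel white reference as the 99th-percentile intensity of
#' each channel and rescales so that reference maps to 255, controlling for
#' minor scanner illumination differences between slides. Values are clipped
#' to `[0, 255]`.
#'
#' @param image A [slide_image()].
#' @param reference_quantile Quantile used as the white reference (default 0.99).
#' @return A white-balanced `slide_image`.
#' @export
white_balance <- function(image, reference_quantile = 0.99) {
  stopifnot(inherits(image, "slide_image"))
  px <- image$pixels
  out <- px
  for (ch in 1:3) {
    ref <- stats::quantile(px[, , ch], probs = reference_quantile,
                           names = FALSE, type = 7)
    if (ref <= 0) stop("no white reference: channel ", ch, " reference is 0")
    out[, , ch] <- pmin(255, pmax(0, px[, , ch] * (255 / ref)))
  }
  image$pixels <- out
  image
}

#' Default H&E stain absorbance basis
#'
#' Standard hematoxylin and eosin unit absorbance directions for optical-density
#' unmixing, with a third direction completing the basis as the normalized cross
#' product. Returned as a 3x3 matrix whose columns are the unit vectors
#' (hematoxylin, eosin, residual).
#'
#' @return 3x3 numeric matrix with unit-norm columns.
#' @export
default_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  m <- cbind(hematoxylin = h, eosin = e, residual = r)
  rownames(m) <- c("R", "G", "B")
  m
}

#' Unmix an H&E image into stain optical densities
#'
#' Converts each pixel to optical density, `OD = -log10(max(I, 1) / 255)` per
#' channel, and solves the 3x3 linear system projecting the pixel OD vector
#' onto the stain absorbance basis. Stains mix additively in OD, so this
#' recovers per-stain densities; negative solutions are clipped to 0.
#'
#' @param image A [slide_image()].
#' @param stain_vectors 3x3 matrix of unit absorbance directions (columns:
#'   hematoxylin, eosin, residual); default [default_stain_vectors()].
#' @return A `stain_channels` object with matrices `hematoxylin_od`,
#'   `eosin_od`, `residual_od` and the basis used.
#' @export
color_deconvolve <- function(image, stain_vectors = default_stain_vectors()) {
  stopifnot(inherits(image, "slide_image"))
  sv <- as.matrix(stain_vectors)
  if (!all(dim(sv) == c(3L, 3L))) stop("stain_vectors must be 3x3")
  norms <- sqrt(colSums(sv^2))
  if (any(abs(norms - 1) > 1e-6)) sv <- sweep(sv, 2, norms, "/")
  if (abs(det(sv)) < 1e-8) stop("degenerate stain basis")
  d <- dim(image$pixels)
  od <- -log10(pmax(image$pixels, 1) / 255)
  odm <- matrix(od, nrow = d[1] * d[2], ncol = 3)  # pixels x RGB channels
  dens <- odm %*% t(solve(sv))                     # solve sv %*% dens = od
  dens[dens < 0] <- 0
  structure(
    list(hematoxylin_od = matrix(dens[, 1], d[1], d[2]),
         eosin_od       = matrix(dens[, 2], d[1], d[2]),
         residual_od    = matrix(dens[, 3], d[1], d[2]),
         stain_vectors  = sv),
    class = "stain_channels")
}

# HSV saturation of a single-stain rendering I = 255 * 10^(-od * v), per pixel.
# For positive RGB triples saturation is (max - min) / max and the 255 scale
# cancels, so work directly on the transmittance 10^(-od * v).
stain_saturation <- function(od, v) {
  tr_min <- 10^(-od * max(v))
  tr_max <- 10^(-od * min(v))
  s <- 1 - tr_min / tr_max
  s[od <= 0] <- 0
  s
}

#' Label pixels by dominant stain
#'
#' Re-renders each unmixed stain as its single-stain RGB image, converts to HSV
#' and compares the stains' color saturations per pixel: the greater saturation
#' wins (hematoxylin -> epithelium, eosin -> stroma). Pixels whose saturations
#' both fall below `sat_threshold_fraction` of the maximum saturation are white
#' space and labelled `NO_STAIN`; exact ties above threshold are also
#' `NO_STAIN` (conservative, deterministic).
#'
#' @param channels A `stain_channels` object from [color_deconvolve()].
#' @param sat_threshold_fraction Fraction of the maximum saturation below which
#'   a pixel is unstained; default 0.1 (the "1/10th maximum" rule).
#' @param max_saturation `"absolute"` (maximum attainable saturation, 1.0;
#'   default) or `"image"` (maximum observed saturation in this image).
#' @return A `binary_stain_map`: a factor matrix `labels` with levels
#'   HEMATOXYLIN, EOSIN, NO_STAIN.
#' @export
binarize_stains <- function(channels, sat_threshold_fraction = 0.1,
                            max_saturation = c("absolute", "image")) {
  stopifnot(inherits(channels, "stain_channels"))
  max_saturation <- match.arg(max_saturation)
  if (!(sat_threshold_fraction > 0 && sat_threshold_fraction < 1))
    stop("sat_threshold_fraction must be in (0, 1)")
  sv <- channels$stain_vectors
  sat_h <- stain_saturation(channels$hematoxylin_od, sv[, 1])
  sat_e <- stain_saturation(channels$eosin_od, sv[, 2])
  ref <- switch(max_saturation,
                absolute = 1.0,
                image = max(sat_h, sat_e))
  thr <- sat_threshold_fraction * ref
  lab <- matrix(STAIN_LEVELS[3], nrow(sat_h), ncol(sat_h))
  lab[sat_h > sat_e & sat_h >= thr] <- STAIN_LEVELS[1]
  lab[sat_e > sat_h & sat_e >= thr] <- STAIN_LEVELS[2]
  structure(list(labels = lab), class = "binary_stain_map")
}

#' Voxelized epithelium/stroma/adipose volume fractions
#'
#' Tiles the binary stain map from the top-left into square voxels of physical
#' side `voxel_size` micrometres (side in pixels = `round(voxel_size *
#' resolution / 1000)`), and per voxel reports the fraction of hematoxylin
#' (epithelium), eosin (stroma), and no-stain (adipose) pixels. Edge voxels use
#' whatever pixels are available, so the three fractions sum to 1 exactly in
#' every voxel.
#'
#' @param labels A `binary_stain_map` from [binarize_stains()].
#' @param resolution Pixels per mm of the parent slide.
#' @param voxel_size Voxel side in micrometres; default 200.
#' @return A `fraction_map` with matrices `epithelium`, `stroma`, `adipose`,
#'   the voxel geometry, and `voxel_size`.
#' @export
compute_fractions <- function(labels, resolution, voxel_size = 200) {
  stopifnot(inherits(labels, "binary_stain_map"))
  lab <- labels$labels
  if (length(lab) == 0L) stop("empty label map")
  side <- round(voxel_size * resolution / 1000)
  if (side < 1) stop("voxel smaller than one pixel at this resolution")
  nr <- nrow(lab); nc <- ncol(lab)
  vr <- ((seq_len(nr) - 1L) %/% side) + 1L
  vc <- ((seq_len(nc) - 1L) %/% side) + 1L
  nvr <- max(vr); nvc <- max(vc)
  vox <- matrix(vr, nr, nc) + (matrix(vc, nr, nc, byrow = TRUE) - 1L) * nvr
  counts <- matrix(0, nvr * nvc, 3,
                   dimnames = list(NULL, STAIN_LEVELS))
  for (k in 1:3) {
    idx <- vox[lab == STAIN_LEVELS[k]]
    if (length(idx))
      counts[, k] <- tabulate(idx, nbins = nvr * nvc)
  }
  tot <- rowSums(counts)
  frac <- counts / tot
  structure(
    list(epithelium = matrix(frac[, 1], nvr, nvc),
         stroma     = matrix(frac[, 2], nvr, nvc),
         adipose    = matrix(frac[, 3], nvr, nvc),
         voxel_size = voxel_size,
         pixels_per_voxel = side,
         rows = nvr, cols = nvc),
    class = "fraction_map")
}

#' Construct a region-of-interest mask
#'
#' @param mask Logical matrix aligned to its parent map grid; at least one
#'   `TRUE` pixel.
#' @param label Optional lesion class annotation.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(mask, label = NA_character_) {
  mask <- if (is.matrix(mask)) mask else as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("ROI mask has no true pixels")
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' ROI summary statistics
#'
#' Sample mean and standard deviation (n - 1 denominator) of each quantity of a
#' fraction map or optical property map over the in-mask (and, for property
#' maps, in-validity) pixels. Specimen-level analysis uses these ROI means, one
#' data point per specimen.
#'
#' @param map A `fraction_map` or [optical_property_map()].
#' @param roi An [roi_mask()] aligned to the map grid, or `NULL` for the whole
#'   map.
#' @return `data.frame` with columns `quantity`, `mean`, `sd`, `n`.
#' @export
roi_statistics <- function(map, roi = NULL) {
  if (inherits(map, "fraction_map")) {
    qs <- list(epithelium = map$epithelium, stroma = map$stroma,
               adipose = map$adipose)
    valid <- matrix(TRUE, nrow(map$epithelium), ncol(map$epithelium))
  } else if (inherits(map, "optical_property_map")) {
    qs <- list(mus_prime = map$mus_prime, gamma = map$gamma,
               b_power = map$b_power)
    valid <- map$valid_mask
  } else stop("map must be a fraction_map or optical_property_map")
  sel <- valid
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    if (!all(dim(roi$mask) == dim(valid)))
      stop("ROI mask not aligned to map grid")
    sel <- sel & roi$mask
  }
  if (!any(sel)) stop("empty ROI")
  out <- lapply(names(qs), function(nm) {
    v <- qs[[nm]][sel]
    data.frame(quantity = nm, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
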