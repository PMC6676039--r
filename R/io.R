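# Readers and writers. Images use the plain-text netpbm formats (ASCII PPM
# for RGB, ASCII PGM for masks and label maps); tabular data are CSV; models
# and reports are JSON. All writers are deterministic.

pnm_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- unlist(strsplit(paste(lines, collapse = " "), "[ \t]+"))
  toks[nzchar(toks)]
}

#' Read / write an ASCII PPM (P3) RGB image
#'
#' @param path File path.
#' @return `read_ppm`: numeric array `rows x cols x 3` in `[0, 255]`.
#' @export
read_ppm <- function(path) {
  toks <- pnm_tokens(path)
  if (toks[1] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc * 3) stop("corrupt PPM: ", path)
  vals <- vals * (255 / maxval)
  px <- array(0, c(nr, nc, 3))
  # PPM stores row-major, channel-interleaved
  for (ch in 1:3)
    px[, , ch] <- matrix(vals[seq(ch, length(vals), by = 3)],
                         nr, nc, byrow = TRUE)
  px
}

#' @param pixels Array `rows x cols x 3` in `[0, 255]`.
#' @rdname read_ppm
#' @export
write_ppm <- function(pixels, path) {
  d <- dim(pixels)
  inter <- integer(d[1] * d[2] * 3)
  for (ch in 1:3)
    inter[seq(ch, length(inter), by = 3)] <- as.vector(t(pixels[, , ch]))
  inter <- as.integer(round(pmin(255, pmax(0, inter))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255",
               paste(inter, collapse = " ")), con)
  invisible(path)
}

#' Read / write an ASCII PGM (P2) single-channel image
#'
#' Used for ROI masks (nonzero = in ROI) and integer label maps.
#'
#' @param path File path.
#' @return `read_pgm`: numeric matrix.
#' @export
read_pgm <- function(path) {
  toks <- pnm_tokens(path)
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  nc <- as.integer(toks[2]); nr <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM: ", path)
  matrix(vals, nr, nc, byrow = TRUE)
}

#' @param mat Numeric/integer matrix.
#' @param maxval Declared maximum value; default 255.
#' @rdname read_pgm
#' @export
write_pgm <- function(mat, path, maxval = 255) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval),
               paste(as.integer(round(t(mat))), collapse = " ")), con)
  invisible(path)
}

# Categorical label matrix <-> PGM with integer codes 1..k (0 unused).
write_label_pgm <- function(labels, path, levels) {
  codes <- matrix(match(labels, levels), nrow(labels), ncol(labels))
  if (anyNA(codes)) stop("labels outside declared levels")
  write_pgm(codes, path, maxval = length(levels))
}

read_label_pgm <- function(path, levels) {
  codes <- read_pgm(path)
  matrix(levels[codes], nrow(codes), ncol(codes))
}

#' Read an ROI mask
#'
#' Accepts a PGM mask (nonzero = in ROI) or a JSON polygon
#' (`{"vertices": [[row, col], ...]}`, filled by even-odd rule on the given
#' grid).
#'
#' @param path `.pgm` or `.json` file.
#' @param grid `c(rows, cols)`, required for polygon input.
#' @param label Optional lesion annotation.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(path, grid = NULL, label = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    roi_mask(read_pgm(path) != 0, label = label)
  } else if (ext == "json") {
    if (is.null(grid)) stop("grid dimensions required for polygon ROI")
    poly <- jsonlite::fromJSON(path)
    v <- poly$vertices
    if (is.null(v) || ncol(v) != 2) stop("polygon ROI needs a vertices array")
    mask <- matrix(FALSE, grid[1], grid[2])
    for (rr in seq_len(grid[1])) {
      # even-odd rule along each row
      cross <- numeric(0)
      np <- nrow(v)
      for (k in seq_len(np)) {
        a <- v[k, ]; b <- v[if (k == np) 1 else k + 1, ]
        if ((a[1] <= rr && b[1] > rr) || (b[1] <= rr && a[1] > rr))
          cross <- c(cross, a[2] + (rr - a[1]) / (b[1] - a[1]) * (b[2] - a[2]))
      }
      cross <- sort(cross)
      k <- 1
      while (k + 1 <= length(cross)) {
        cc <- seq_len(grid[2])
        mask[rr, cc >= cross[k] & cc <= cross[k + 1]] <- TRUE
        k <- k + 2
      }
    }
    roi_mask(mask, label = label)
  } else stop("unsupported ROI mask format: ", path)
}

COHORT_COLUMNS <- c(
  "specimen_id", "class", "subtype",
  "mus_prime_mean", "mus_prime_sd", "gamma_mean", "gamma_sd",
  "b_power_mean", "b_power_sd",
  "epithelium_mean", "epithelium_sd", "stroma_mean", "stroma_sd",
  "adipose_mean", "adipose_sd")

#' Read / write a cohort table CSV
#'
#' One row per specimen: pathology class, per-property ROI mean/sd, and
#' per-fraction ROI mean/sd. `read_cohort_csv` validates the schema.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv`: validated `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("missing cohort CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(COHORT_COLUMNS, "subtype"), names(df))
  if (length(miss))
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$class), PATHOLOGY_LEVELS)
  if (length(bad))
    stop("cohort CSV has unknown class label(s): ", paste(bad, collapse = ", "))
  for (fr in FRACTIONS) {
    v <- df[[paste0(fr, "_mean")]]
    if (any(v < 0 | v > 1)) stop("fraction means outside [0, 1] in ", path)
  }
  df
}

#' @param cohort Cohort `data.frame`.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a fraction map as CSV
#'
#' Long format: one row per voxel with `row`, `col`, `epithelium`, `stroma`,
#' `adipose`, plus constant `voxel_size` and `pixels_per_voxel` columns.
#'
#' @param fmap A `fraction_map`.
#' @param path CSV file path.
#' @export
write_fraction_map_csv <- function(fmap, path) {
  stopifnot(inherits(fmap, "fraction_map"))
  grid <- expand.grid(row = seq_len(fmap$rows), col = seq_len(fmap$cols))
  df <- data.frame(grid,
                   epithelium = as.vector(fmap$epithelium),
                   stroma = as.vector(fmap$stroma),
                   adipose = as.vector(fmap$adipose),
                   voxel_size = fmap$voxel_size,
                   pixels_per_voxel = fmap$pixels_per_voxel)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fraction_map_csv
#' @export
read_fraction_map_csv <- function(path) {
  df <- utils::read.csv(path)
  nr <- max(df$row); nc <- max(df$col)
  shape <- function(v) matrix(v[order(df$col, df$row)], nr, nc)
  structure(
    list(epithelium = shape(df$epithelium), stroma = shape(df$stroma),
         adipose = shape(df$adipose), voxel_size = df$voxel_size[1],
         pixels_per_voxel = df$pixels_per_voxel[1], rows = nr, cols = nc),
    class = "fraction_map")
}

#' Write / read an optical property map as CSV
#'
#' Long format: `row`, `col`, `mus_prime`, `gamma`, `b_power`, `valid`, with a
#' constant `pixel_size` column (mm).
#'
#' @param map An [optical_property_map()].
#' @param path CSV file path.
#' @export
write_property_map_csv <- function(map, path) {
  stopifnot(inherits(map, "optical_property_map"))
  d <- dim(map$mus_prime)
  grid <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df <- data.frame(grid,
                   mus_prime = as.vector(map$mus_prime),
                   gamma = as.vector(map$gamma),
                   b_power = as.vector(map$b_power),
                   valid = as.integer(as.vector(map$valid_mask)),
                   pixel_size = map$pixel_size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_map_csv
#' @export
read_property_map_csv <- function(path, specimen_id = "unknown") {
  df <- utils::read.csv(path)
  nr <- max(df$row); nc <- max(df$col)
  ord <- order(df$col, df$row)
  shape <- function(v) matrix(v[ord], nr, nc)
  optical_property_map(shape(df$mus_prime), shape(df$gamma),
                       shape(df$b_power), pixel_size = df$pixel_size[1],
                       valid_mask = shape(df$valid) != 0,
                       specimen_id = specimen_id)
}

#' Serialize / load the nine fitted models as JSON
#'
#' @param models Nested list `models[[fraction]][[property]]` of
#'   `scatter_model`s.
#' @param path JSON file path.
#' @export
write_models_json <- function(models, path) {
  ser <- lapply(models, function(per_prop) lapply(per_prop, function(m) {
    list(family = m$family, property_name = m$property_name,
         fraction_name = m$fraction_name, params = as.list(m$params),
         param_cov = m$param_cov, rmse = m$rmse, r2_adj = m$r2_adj,
         sse = m$sse, n_fit = m$n_fit, x_range = m$x_range)
  }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(ser, function(per_prop) lapply(per_prop, function(m) {
    params <- unlist(m$params)
    p <- length(params)
    covvals <- unlist(lapply(m$param_cov, function(rr)
      vapply(rr, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
             numeric(1))))
    cov <- matrix(covvals, p, p, byrow = TRUE,
                  dimnames = list(names(params), names(params)))
    structure(
      list(family = m$family, property_name = m$property_name,
           fraction_name = m$fraction_name, params = params,
           param_cov = cov, rmse = m$rmse, r2_adj = m$r2_adj, sse = m$sse,
           n_fit = m$n_fit, x_range = unlist(m$x_range)),
      class = "scatter_model")
  }))
}

#' Check input files before a run
#'
#' Reports problems without raising: missing files, malformed cohort schema,
#' non-8-bit slide values, and mask/map misalignment. Errors block a run;
#' warnings do not.
#'
#' @param cohort_csv,slide_ppm,mask_pgm,map_csv Optional file paths.
#' @return `data.frame` with columns `level` (`"error"`/`"warning"`),
#'   `message`; zero rows when everything is well formed.
#' @export
validate_inputs <- function(cohort_csv = NULL, slide_ppm = NULL,
                            mask_pgm = NULL, map_csv = NULL) {
  issues <- data.frame(level = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(level, msg)
    issues <<- rbind(issues, data.frame(level = level, message = msg,
                                        stringsAsFactors = FALSE))
  slide_px <- NULL
  if (!is.null(slide_ppm)) {
    if (!file.exists(slide_ppm)) add("error", paste("missing slide:", slide_ppm))
    else slide_px <- tryCatch(read_ppm(slide_ppm), error = function(e) {
      add("error", conditionMessage(e)); NULL
    })
    if (!is.null(slide_px) && (max(slide_px) > 255 || min(slide_px) < 0))
      add("error", "slide channel values outside 8-bit range")
  }
  if (!is.null(cohort_csv)) {
    if (!file.exists(cohort_csv))
      add("error", paste("missing cohort CSV:", cohort_csv))
    else tryCatch(read_cohort_csv(cohort_csv), error = function(e)
      add("error", conditionMessage(e)))
  }
  mapobj <- NULL
  if (!is.null(map_csv)) {
    if (!file.exists(map_csv)) add("error", paste("missing map CSV:", map_csv))
    else mapobj <- tryCatch(read_property_map_csv(map_csv),
                            error = function(e) {
                              add("error", conditionMessage(e)); NULL
                            })
  }
  if (!is.null(mask_pgm)) {
    if (!file.exists(mask_pgm)) add("error", paste("missing mask:", mask_pgm))
    else {
      mk <- tryCatch(read_pgm(mask_pgm), error = function(e) {
        add("error", conditionMessage(e)); NULL
      })
      if (!is.null(mk)) {
        if (!any(mk != 0)) add("warning", "mask has no in-ROI pixels")
        target <- if (!is.null(mapobj)) dim(mapobj$mus_prime)
                  else if (!is.null(slide_px)) dim(slide_px)[1:2] else NULL
        if (!is.null(target) && !all(dim(mk) == target))
          add("error", sprintf(
            "mask grid %dx%d does not align with map/slide grid %dx%d",
            nrow(mk), ncol(mk), target[1], target[2]))
      }
    }
  }
  issues
}
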