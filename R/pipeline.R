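# Leave-one-out cross-validated histology prediction from light-scattering
# properties, epithelium:stroma ratio, three-way threshold classification, and
# soft classification / overlay rendering.

FRACTIONS  <- c("stroma", "epithelium", "adipose")
PROPERTIES <- c("mus_prime", "gamma", "b_power")
CLASS_LEVELS <- c("malignant", "benign", "fat")

# Curve family per fraction is fixed: monotone responses are logistic,
# the peaked epithelium response is Gaussian.
fraction_family <- function(fraction) {
  if (fraction == "epithelium") "gaussian3" else "logistic2"
}

#' Map a pathology label to its classification class
#'
#' Invasive cancer specimens are the malignant class, fibroglandular the
#' benign class, and fat specimens the fat class.
#'
#' @param pathology Character vector over
#'   `{invasive, fibroglandular, fat}`.
#' @return Character vector over `{malignant, benign, fat}`.
#' @export
pathology_to_class <- function(pathology) {
  map <- c(invasive = "malignant", fibroglandular = "benign", fat = "fat")
  if (!all(pathology %in% names(map)))
    stop("unknown pathology label(s): ",
         paste(setdiff(pathology, names(map)), collapse = ", "))
  unname(map[pathology])
}

check_cohort <- function(cohort) {
  need <- c("specimen_id", "class",
            paste0(rep(PROPERTIES, each = 2), c("_mean", "_sd")),
            paste0(rep(FRACTIONS, each = 2), c("_mean", "_sd")))
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  invisible(cohort)
}

#' Fit all nine fraction-versus-property models on a cohort
#'
#' One curve per (fraction, property) pair: logistic for stroma and adipose,
#' Gaussian for epithelium, against each of mu_s', gamma, and B, using
#' specimen ROI means (one point per specimen).
#'
#' @param cohort Cohort table (`data.frame`) with per-specimen
#'   `<property>_mean` and `<fraction>_mean` columns.
#' @return Nested list `models[[fraction]][[property]]` of `scatter_model`s.
#' @export
fit_all_models <- function(cohort) {
  check_cohort(cohort)
  models <- list()
  for (fr in FRACTIONS) {
    models[[fr]] <- list()
    for (pr in PROPERTIES) {
      models[[fr]][[pr]] <- fit_scatter_model(
        cohort[[paste0(pr, "_mean")]], cohort[[paste0(fr, "_mean")]],
        family = fraction_family(fr), property_name = pr, fraction_name = fr)
    }
  }
  models
}

#' Predict tissue fractions from the three scattering properties
#'
#' For each fraction, evaluates its three property models, clips each
#' component prediction to `[0, 1]`, and averages the three. The final
#' fractions are deliberately not renormalized to sum to 1.
#'
#' @param models Nested model list from [fit_all_models()].
#' @param properties `data.frame` (or named list) with columns `mus_prime`,
#'   `gamma`, `b_power`; one row per specimen or pixel.
#' @return `data.frame` with predicted `stroma`, `epithelium`, `adipose` and
#'   the nine clipped component predictions (`<fraction>_from_<property>`).
#' @export
predict_fractions <- function(models, properties) {
  for (fr in FRACTIONS) for (pr in PROPERTIES)
    if (is.null(models[[fr]][[pr]]))
      stop("missing model for ", fr, " ~ ", pr)
  miss <- setdiff(PROPERTIES, names(properties))
  if (length(miss)) stop("missing properties: ", paste(miss, collapse = ", "))
  n <- length(properties[[PROPERTIES[1]]])
  out <- data.frame(row.names = seq_len(n))
  for (fr in FRACTIONS) {
    comps <- sapply(PROPERTIES, function(pr) {
      pmin(1, pmax(0, predict(models[[fr]][[pr]], properties[[pr]])))
    })
    comps <- matrix(comps, nrow = n,
                    dimnames = list(NULL, paste0(fr, "_from_", PROPERTIES)))
    out[[fr]] <- rowMeans(comps)
    out <- cbind(out, comps)
  }
  out
}

#' Epithelium to stroma ratio
#'
#' The diagnostic ratio: more epithelium than stroma (> 1) indicates elevated
#' cellularity, the malignancy signature in glandular tissue. Stroma 0 with
#' positive epithelium gives `+Inf`; both 0 gives 0 (no epithelium, benign).
#'
#' @param epithelium,stroma Predicted fractions in `[0, 1]` (vectorized).
#' @return Nonnegative ratio(s), possibly `Inf`.
#' @export
ep_st_ratio <- function(epithelium, stroma) {
  r <- ifelse(stroma > 0, epithelium / stroma,
              ifelse(epithelium > 0, Inf, 0))
  as.numeric(r)
}

#' Threshold classification into malignant / benign / fat
#'
#' Adipose above `fat_threshold` is fat; otherwise an epithelium:stroma ratio
#' above `ratio_threshold` is malignant, else benign. Both inequalities are
#' strict, so boundary cases fall to the benign/non-fat side.
#'
#' @param epithelium,stroma,adipose Predicted fractions (vectorized).
#' @param fat_threshold Adipose fraction threshold; default 0.5.
#' @param ratio_threshold Epithelium:stroma ratio threshold; default 1.
#' @return Character vector over `{malignant, benign, fat}`.
#' @export
classify_fractions <- function(epithelium, stroma, adipose,
                               fat_threshold = 0.5, ratio_threshold = 1) {
  ratio <- ep_st_ratio(epithelium, stroma)
  ifelse(adipose > fat_threshold, "fat",
         ifelse(ratio > ratio_threshold, "malignant", "benign"))
}

#' Leave-one-out cross-validated fraction prediction
#'
#' For each specimen in turn, refits all nine models on the remaining
#' specimens and predicts the held-out specimen's fractions; no fold's models
#' ever see their test specimen. A fold whose training fit fails is recorded
#' (`fold_ok = FALSE`, `NA` predictions), never silently dropped.
#'
#' @param cohort Cohort table with property and fraction means.
#' @param fat_threshold,ratio_threshold Classification thresholds.
#' @return `data.frame`: one row per specimen with predicted fractions,
#'   component predictions, `ep_st_ratio`, `predicted_class`, `fold_ok`.
#' @export
loo_cv <- function(cohort, fat_threshold = 0.5, ratio_threshold = 1) {
  check_cohort(cohort)
  n <- nrow(cohort)
  if (n < 4) stop("LOO-CV needs at least 4 specimens")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    train <- cohort[-i, , drop = FALSE]
    test <- cohort[i, , drop = FALSE]
    pred <- tryCatch({
      models <- fit_all_models(train)
      props <- list(mus_prime = test$mus_prime_mean,
                    gamma = test$gamma_mean,
                    b_power = test$b_power_mean)
      predict_fractions(models, props)
    }, error = function(e) NULL)
    if (is.null(pred)) {
      empty <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, 12),
        c(FRACTIONS, paste0(rep(FRACTIONS, each = 3), "_from_", PROPERTIES)))))
      rows[[i]] <- cbind(
        data.frame(specimen_id = test$specimen_id, stringsAsFactors = FALSE),
        empty,
        data.frame(ep_st_ratio = NA_real_, predicted_class = NA_character_,
                   fold_ok = FALSE, stringsAsFactors = FALSE))
    } else {
      ratio <- ep_st_ratio(pred$epithelium, pred$stroma)
      cls <- classify_fractions(pred$epithelium, pred$stroma, pred$adipose,
                                fat_threshold, ratio_threshold)
      rows[[i]] <- cbind(
        data.frame(specimen_id = test$specimen_id, stringsAsFactors = FALSE),
        pred,
        data.frame(ep_st_ratio = ratio, predicted_class = cls,
                   fold_ok = TRUE, stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Class display colors (RGB in [0,1]): purple for malignant (epithelium-rich),
# pink for benign (stroma-rich, "no epithelium" end), yellow for fat.
CLASS_COLORS <- rbind(
  malignant = c(0.50, 0.00, 0.50),
  benign    = c(1.00, 0.41, 0.71),
  fat       = c(1.00, 0.85, 0.00))

#' Soft classification map
#'
#' Per-pixel class color whose saturation encodes distance from the decision
#' threshold: glandular pixels use `min(1, |ratio - 1|)` (white at ratio 1,
#' fully saturated at ratio 0 or 2), fat pixels use
#' `min(1, |adipose - 0.5| / 0.5)`. Saturation 0 renders white (uncertain).
#'
#' @param epithelium,stroma,adipose Matrices of per-pixel predicted fractions.
#' @param fat_threshold,ratio_threshold Classification thresholds.
#' @return A `soft_class_map`: matrices `class` and `saturation`, plus an
#'   `rgb` array (`rows x cols x 3`, values in `[0, 1]`).
#' @export
soft_classification_map <- function(epithelium, stroma, adipose,
                                    fat_threshold = 0.5, ratio_threshold = 1) {
  d <- dim(epithelium)
  ratio <- matrix(ep_st_ratio(epithelium, stroma), d[1], d[2])
  cls <- matrix(classify_fractions(epithelium, stroma, adipose,
                                   fat_threshold, ratio_threshold), d[1], d[2])
  sat <- ifelse(cls == "fat",
                pmin(1, abs(adipose - fat_threshold) / fat_threshold),
                pmin(1, abs(ratio - ratio_threshold)))
  rgb <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    col <- matrix(CLASS_COLORS[cls, ch], d[1], d[2])
    rgb[, , ch] <- (1 - sat) * 1 + sat * col
  }
  structure(list(class = cls, saturation = sat, ratio = ratio, rgb = rgb),
            class = "soft_class_map")
}

#' Overlay a soft classification map on a specimen photograph
#'
#' Alpha-composites the class colors onto the photograph with per-pixel alpha
#' equal to the soft-map saturation, so an uncertain classification (ratio near
#' 1) is transparent. Fat pixels are rendered fully transparent: adipose is
#' distinguishable by visual inspection and is not overlaid.
#'
#' @param soft_map A `soft_class_map`.
#' @param photo RGB array (`rows x cols x 3`) on the same grid; values either
#'   in `[0, 1]` or `[0, 255]` (detected from the maximum).
#' @return RGB array on the photo's scale.
#' @export
overlay_on_photograph <- function(soft_map, photo) {
  stopifnot(inherits(soft_map, "soft_class_map"))
  d <- dim(soft_map$class)
  if (!all(dim(photo)[1:2] == d) || dim(photo)[3] != 3)
    stop("photo grid does not match soft map")
  scale <- if (max(photo) > 1) 255 else 1
  alpha <- soft_map$saturation
  alpha[soft_map$class == "fat"] <- 0
  out <- photo
  for (ch in 1:3) {
    col <- matrix(CLASS_COLORS[soft_map$class, ch], d[1], d[2]) * scale
    out[, , ch] <- alpha * col + (1 - alpha) * photo[, , ch]
  }
  out
}
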