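#' Regional mean blood flow
#'
#' Arithmetic mean of the blood-flow pixels under each of the 14 region
#' codes of a projected mask set. Regions whose mask is empty are marked
#' missing (`NA`) rather than imputed.
#'
#' @param blood H x W matrix of positive relative perfusion values (a
#'   blood-flow frame).
#' @param masks a `region_mask_set` sharing the frame's shape.
#' @return A `region_means` data frame with columns `code` (1-14),
#'   `region` (abbreviation), `side` and `mean_flow`.
#' @export
regional_mean_flow <- function(blood, masks) {
  lab <- if (inherits(masks, "region_mask_set")) masks$label else masks
  if (!identical(dim(blood), dim(lab)))
    stop("blood frame and masks must share shape", call. = FALSE)
  if (any(blood <= 0) || any(!is.finite(blood)))
    stop("blood-flow values must be positive and finite", call. = FALSE)
  sums <- rep(NA_real_, 14); ns <- tabulate(lab[lab > 0L], nbins = 14L)
  if (all(ns == 0L))
    stop("all 14 region masks are empty: segmentation failed", call. = FALSE)
  idx <- lab > 0L
  acc <- rowsum(blood[idx], lab[idx])
  sums[as.integer(rownames(acc))] <- acc
  means <- ifelse(ns > 0L, sums / ns, NA_real_)
  structure(data.frame(
    code = 1:14,
    region = face_regions$abbrev[c(1:7, 1:7)],
    side = rep(c("L", "R"), each = 7L),
    mean_flow = means,
    stringsAsFactors = FALSE), class = c("region_means", "data.frame"))
}

# region_means constructor from a named 14-vector in code order 1..14
region_means_from_vector <- function(v) {
  structure(data.frame(
    code = 1:14,
    region = face_regions$abbrev[c(1:7, 1:7)],
    side = rep(c("L", "R"), each = 7L),
    mean_flow = as.numeric(v),
    stringsAsFactors = FALSE), class = c("region_means", "data.frame"))
}

#' Order regional means by affected/healthy side and min-normalise
#'
#' Builds the 14-element classifier input
#' `[A_B, A_E, A_N, A_C, A_MU, A_MC, A_MB, H_B, ..., H_MB]`: the A half
#' holds the affected (ill) side's regional means in region-index order,
#' the H half the healthy side's. All 14 values are divided by
#' `Volume_min`, the minimum over the 14 raw means, yielding a
#' scale-free relative perfusion vector with minimum exactly 1 —
#' LSCI devices report perfusion only in relative units, so any global
#' scale must cancel.
#'
#' @param means a `region_means` (no missing values allowed).
#' @param ill_side `"L"` or `"R"`: the paralysed facial side. For
#'   healthy (grade I) participants the right side is used by convention.
#' @return A `feature_vector`: named numeric vector of length 14
#'   (names `A_B` ... `H_MB`) with attribute `volume_min` (the divisor,
#'   kept for audit; raw means are recoverable as `values * volume_min`).
#' @export
order_and_normalize <- function(means, ill_side = c("L", "R")) {
  ill_side <- match.arg(ill_side)
  if (any(is.na(means$mean_flow))) {
    bad <- means[is.na(means$mean_flow), ]
    stop("missing regional mean(s): ",
         paste(paste0(bad$region, "_", bad$side), collapse = ", "),
         call. = FALSE)
  }
  healthy_side <- if (ill_side == "L") "R" else "L"
  pick <- function(s) {
    v <- means$mean_flow[means$side == s][order(means$code[means$side == s])]
    v
  }
  raw <- c(pick(ill_side), pick(healthy_side))
  vmin <- min(raw)
  values <- raw / vmin
  names(values) <- c(paste0("A_", face_regions$abbrev),
                     paste0("H_", face_regions$abbrev))
  structure(values, volume_min = vmin, ill_side = ill_side,
            class = "feature_vector")
}

#' Healthy-to-affected perfusion ratio of a region
#'
#' `P_r = P_h / P_a`, the ratio of the healthy-side regional mean flow to
#' the affected-side one. A value of 1 indicates symmetric perfusion;
#' larger values indicate greater paralysis-associated asymmetry.
#'
#' @param means a `region_means`.
#' @param region_code region index 1-7.
#' @param ill_side the affected side, `"L"` or `"R"`.
#' @return Scalar ratio.
#' @export
asymmetry_ratio <- function(means, region_code, ill_side = c("L", "R")) {
  ill_side <- match.arg(ill_side)
  if (!(region_code %in% 1:7))
    stop("region_code must be in 1..7", call. = FALSE)
  healthy_side <- if (ill_side == "L") "R" else "L"
  p_a <- means$mean_flow[means$code == region_label_code(region_code, ill_side)]
  p_h <- means$mean_flow[means$code == region_label_code(region_code, healthy_side)]
  if (is.na(p_a) || is.na(p_h))
    stop("regional mean missing for region ", region_code, call. = FALSE)
  if (p_a <= 0)
    stop("nonphysical input: affected-side mean is not positive", call. = FALSE)
  p_h / p_a
}

#' Write / read a cohort feature table as CSV
#'
#' One row per patient: `patient_id`, `ill_side`, `hb_grade`, the 14
#' feature columns `A_B` ... `H_MB`, and `volume_min`.
#'
#' @param features data frame as produced by [extract_cohort_features()].
#' @param path CSV path.
#' @return `read_features_csv` returns the data frame.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "ill_side", "hb_grade", feature_names())
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("feature CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

feature_names <- function() {
  c(paste0("A_", face_regions$abbrev), paste0("H_", face_regions$abbrev))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Relative perfusion features (ill side %s, Volume_min %.4g):\n",
              attr(x, "ill_side"), attr(x, "volume_min")))
  print(round(unclass(x), 4))
  invisible(x)
}
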