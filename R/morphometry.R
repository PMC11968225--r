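#' Implant volume from caliper dimensions
#'
#' Computes implant volume from caliper length, width and height.  The
#' default treats the implant as an ellipsoid, `V = pi/6 * l * w * h`; a
#' rectangular-box formula `V = l * w * h` is also available.  Because fold
#' changes are ratios, the constant cancels and the choice does not affect
#' any fold-change result.
#'
#' @param length_mm,width_mm,height_mm Caliper dimensions (mm, > 0);
#'   vectorized.
#' @param formula `"ellipsoid"` (default) or `"box"`.
#' @return Volume in mm^3.
#' @export
#' @examples
#' implant_volume(2, 2, 2)              # pi/6 * 8
#' implant_volume(2, 2, 2, "box")       # 8
implant_volume <- function(length_mm, width_mm, height_mm,
                           formula = c("ellipsoid", "box")) {
  formula <- match.arg(formula)
  if (any(c(length_mm, width_mm, height_mm) <= 0, na.rm = TRUE))
    stopf("caliper dimensions must be > 0")
  v <- length_mm * width_mm * height_mm
  if (formula == "ellipsoid") v <- v * pi / 6
  v
}

#' Volume and height fold changes of implants over time
#'
#' For each implant, divides every timepoint's volume and height by its
#' measurement at timepoint 0 (implantation).  Group-level mean and SD
#' summaries are available via [summary.fold_changes()].
#'
#' @param records A `caliper_records` data frame (see
#'   [generate_caliper_series()]) with columns `implant_id`, `group`,
#'   `timepoint`, `height_mm`, `volume_mm3`.
#' @return `fold_changes` data frame: `implant_id`, `group`, `timepoint`,
#'   `volume_fold`, `height_fold`.
#' @export
fold_change <- function(records) {
  need <- c("implant_id", "timepoint", "height_mm", "volume_mm3")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records lack columns: %s", paste(miss, collapse = ", "))
  base <- records[records$timepoint == 0, ]
  no_base <- setdiff(unique(records$implant_id), base$implant_id)
  if (length(no_base))
    stopf("no timepoint-0 baseline for implant(s): %s", paste(no_base, collapse = ", "))
  if (anyDuplicated(base$implant_id))
    stopf("multiple timepoint-0 records for implant(s): %s",
          paste(unique(base$implant_id[duplicated(base$implant_id)]), collapse = ", "))
  i <- match(records$implant_id, base$implant_id)
  out <- data.frame(implant_id = records$implant_id,
                    group = if ("group" %in% names(records)) records$group else NA,
                    timepoint = records$timepoint,
                    volume_fold = records$volume_mm3 / base$volume_mm3[i],
                    height_fold = records$height_mm / base$height_mm[i])
  out <- out[order(out$implant_id, out$timepoint), ]
  rownames(out) <- NULL
  class(out) <- c("fold_changes", "data.frame")
  out
}

#' Group-level fold-change summary
#'
#' Mean and SD of volume and height fold changes per group and timepoint,
#' plus the mean percent change in volume relative to implantation.
#'
#' @param object A `fold_changes` table from [fold_change()].
#' @param ... Unused.
#' @return Data frame with one row per group x timepoint.
#' @export
summary.fold_changes <- function(object, ...) {
  key <- interaction(object$group, object$timepoint, drop = TRUE)
  agg <- function(v, f) as.vector(tapply(v, key, f))
  out <- data.frame(group = tapply(as.character(object$group), key, `[`, 1),
                    timepoint = tapply(object$timepoint, key, `[`, 1),
                    n = as.vector(table(key)),
                    volume_fold_mean = agg(object$volume_fold, mean),
                    volume_fold_sd = agg(object$volume_fold, sd),
                    height_fold_mean = agg(object$height_fold, mean),
                    height_fold_sd = agg(object$height_fold, sd))
  out$volume_pct_change <- (out$volume_fold_mean - 1) * 100
  out <- out[order(out$group, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Flag caliper outliers by robust deviation
#'
#' Optional replacement for proprietary regression-based outlier removal:
#' flags fold changes more than `k` median absolute deviations from their
#' group x timepoint median.  Off by default in all pipelines; flagged ids
#' are reported, never silently dropped.
#'
#' @param folds A `fold_changes` table.
#' @param k MAD multiplier (default 3.5).
#' @return The table with a logical `outlier` column.
#' @export
flag_outliers_mad <- function(folds, k = 3.5) {
  key <- interaction(folds$group, folds$timepoint, drop = TRUE)
  out <- rep(FALSE, nrow(folds))
  for (g in levels(key)) {
    i <- which(key == g)
    v <- folds$volume_fold[i]
    m <- median(v); s <- median(abs(v - m)) * 1.4826
    if (s > 0) out[i] <- abs(v - m) / s > k
  }
  folds$outlier <- out
  folds
}
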