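# Rule-based expert system: a fixed decision tree over the aggregated
# features, mirroring how veterinary experts combine the three locomotion
# indicators. The tree structure is fixed; only the thresholds are
# configurable (or calibrated from labeled data).

#' Expert-tree threshold configuration
#'
#' The tree routes a passage as follows (ties take the branch stated here):
#' \enumerate{
#'   \item `head_drop >= theta_head_7` -> grade 7 (severe, head bob);
#'   \item else `spine_value >= theta_spine_12_36` -> grades 1-2 side,
#'     where `spine_value >= theta_spine_1_2` -> 1, else 2;
#'   \item else `legs_value <= theta_legs_3_46` -> grade 3;
#'   \item else `head_drop >= theta_head_45_6` -> grade 6, else the merged
#'     4-5 leaf.
#' }
#' Grades 4 and 5 are merged: their clinical presentations differ only
#' slightly and experts group them; the merged leaf is emitted as the
#' ordinal `merged_45_output` (default 4.5, so it is within one grade of
#' both true 4 and true 5).
#'
#' @param theta_head_7 head-drop threshold for the grade-7 branch.
#' @param theta_spine_12_36 spine threshold separating grades 1-2 from 3-6.
#' @param theta_spine_1_2 spine threshold separating grade 1 from 2; must be
#'   `>= theta_spine_12_36`.
#' @param theta_legs_3_46 legs threshold separating grade 3 from 4-6.
#' @param theta_head_45_6 head-drop threshold separating 4-5 from 6.
#' @param merged_45_output ordinal emitted for the merged 4-5 leaf.
#' @return An object of class `expert_config`.
#' @export
expert_config <- function(theta_head_7, theta_spine_12_36, theta_spine_1_2,
                          theta_legs_3_46, theta_head_45_6,
                          merged_45_output = 4.5) {
  cfg <- list(theta_head_7 = theta_head_7,
              theta_spine_12_36 = theta_spine_12_36,
              theta_spine_1_2 = theta_spine_1_2,
              theta_legs_3_46 = theta_legs_3_46,
              theta_head_45_6 = theta_head_45_6,
              merged_45_output = merged_45_output)
  if (!all(vapply(cfg, function(v) is.numeric(v) && is.finite(v), TRUE)))
    stop("expert_config: all thresholds must be finite numbers")
  if (cfg$theta_spine_1_2 < cfg$theta_spine_12_36)
    stop("expert_config: theta_spine_1_2 must be >= theta_spine_12_36")
  structure(cfg, class = "expert_config")
}

#' @export
print.expert_config <- function(x, ...) {
  cat("Expert-tree thresholds:\n")
  for (k in setdiff(names(x), "merged_45_output"))
    cat(sprintf("  %-18s %.4f\n", k, x[[k]]))
  cat(sprintf("  merged 4-5 leaf -> %s\n", format(x$merged_45_output)))
  invisible(x)
}

#' Classify a passage with the expert tree
#'
#' Routes an aggregated feature vector through the fixed decision tree (see
#' [expert_config()]). Sentinel (`NA`) head features, which arise on
#' zero-step passages, take the non-7 and merged-4-5 branches: absence of
#' evidence of head bobbing is read as no head bobbing. The routing is
#' monotone: increasing `head_drop` never lowers the grade, increasing
#' `spine_value` never raises it, increasing `legs_value` never lowers it.
#'
#' @param features a one-row data frame (or row-bindable table) with
#'   columns `spine_value`, `head_drop`, `legs_value` (see
#'   [build_features()]); vectorized over rows.
#' @param config an [expert_config()].
#' @return Numeric vector of grades in `{1, 2, 3, merged_45_output, 6, 7}`.
#' @export
classify_expert <- function(features, config) {
  stopifnot(inherits(config, "expert_config"))
  n <- nrow(features)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hd <- features$head_drop[i]
    sp <- features$spine_value[i]
    lg <- features$legs_value[i]
    out[i] <-
      if (!is.na(hd) && hd >= config$theta_head_7) 7
      else if (!is.na(sp) && sp >= config$theta_spine_12_36) {
        if (sp >= config$theta_spine_1_2) 1 else 2
      } else if (!is.na(lg) && lg <= config$theta_legs_3_46) 3
      else if (!is.na(hd) && hd >= config$theta_head_45_6) 6
      else config$merged_45_output
  }
  out
}

#' Calibrate expert-tree thresholds from labeled features
#'
#' Stands in for the threshold elicitation that veterinary experts perform
#' on real herds: each threshold is set to the midpoint between the
#' class-conditional medians of the two grades adjacent to its split (the
#' boundary classes, e.g. grades 2 and 3 for the 1-2 versus 3-6 spine
#' split). When a boundary grade has no rows, the next grade on the same
#' side of the split is used; a split with no data on one side is an error
#' naming the split. Deterministic.
#'
#' @param features_table data frame with columns `spine_value`, `head_drop`,
#'   `legs_value` and a `label` column of true grades in 1..7.
#' @param merged_45_output ordinal for the merged 4-5 leaf.
#' @return An [expert_config()].
#' @export
calibrate_thresholds <- function(features_table, merged_45_output = 4.5) {
  lab <- features_table$label
  if (is.null(lab) || all(is.na(lab)))
    stop("calibrate_thresholds: features_table must carry labels")
  # median of the boundary class; `grades` ordered from the split outward
  side_median <- function(col, grades, split) {
    for (g in grades) {
      v <- features_table[[col]][lab == g]
      v <- v[!is.na(v)]
      if (length(v)) return(stats::median(v))
    }
    stop(sprintf("split '%s': no data for grades %s", split,
                 paste(grades, collapse = ",")))
  }
  mid <- function(a, b) (a + b) / 2
  expert_config(
    theta_head_7 = mid(side_median("head_drop", 6:1, "7 vs 1-6"),
                       side_median("head_drop", 7, "7 vs 1-6")),
    theta_spine_12_36 = mid(side_median("spine_value", 3:6, "1-2 vs 3-6"),
                            side_median("spine_value", 2:1, "1-2 vs 3-6")),
    theta_spine_1_2 = mid(side_median("spine_value", 2, "1 vs 2"),
                          side_median("spine_value", 1, "1 vs 2")),
    theta_legs_3_46 = mid(side_median("legs_value", 3, "3 vs 4-6"),
                          side_median("legs_value", 4:6, "3 vs 4-6")),
    theta_head_45_6 = mid(side_median("head_drop", 5:4, "4-5 vs 6"),
                          side_median("head_drop", 6, "4-5 vs 6")),
    merged_45_output = merged_45_output
  )
}
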