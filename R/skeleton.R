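#' The 22-keypoint cow skeleton
#'
#' Defines the named anatomical landmarks used throughout the package, their
#' fixed order, and their anatomical groups. The order matches the annotation
#' scheme of the pose model the package consumes: Eye, Neck, four spine
#' points, then four points per leg (front legs carry a Carpal, rear legs an
#' Ankle and a Knee). "FR"/"FL"/"BR"/"BL" denote front-right, front-left,
#' back-right and back-left limbs, viewed from the side.
#'
#' @return An object of class `cow_skeleton`: a list with
#'   \describe{
#'     \item{names}{character vector of the 22 keypoint labels, in index order}
#'     \item{groups}{named list mapping group name (`spine`, `head`, `leg_FR`,
#'       `leg_FL`, `leg_BR`, `leg_BL`) to keypoint labels}
#'     \item{hoof_set}{the four `*_Hoof` labels}
#'   }
#' @examples
#' sk <- cow_skeleton()
#' length(sk$names)      # 22
#' sk$groups$spine       # Neck and the four spine points
#' @export
cow_skeleton <- function() {
  names <- c(
    "Eye", "Neck", "Spine_1", "Spine_2", "Spine_3", "Spine_4",
    "FR_Hoof", "FR_Fetlock", "FR_Carpal", "FR_Elbow",
    "FL_Hoof", "FL_Fetlock", "FL_Carpal", "FL_Elbow",
    "BL_Hoof", "BL_Fetlock", "BL_Ankle", "BL_Knee",
    "BR_Hoof", "BR_Fetlock", "BR_Ankle", "BR_Knee"
  )
  groups <- list(
    spine  = c("Neck", "Spine_1", "Spine_2", "Spine_3", "Spine_4"),
    head   = "Eye",
    leg_FR = c("FR_Hoof", "FR_Fetlock", "FR_Carpal", "FR_Elbow"),
    leg_FL = c("FL_Hoof", "FL_Fetlock", "FL_Carpal", "FL_Elbow"),
    leg_BR = c("BR_Hoof", "BR_Fetlock", "BR_Ankle", "BR_Knee"),
    leg_BL = c("BL_Hoof", "BL_Fetlock", "BL_Ankle", "BL_Knee")
  )
  hoof_set <- c("FR_Hoof", "FL_Hoof", "BR_Hoof", "BL_Hoof")
  stopifnot(
    length(names) == 22L, !anyDuplicated(names),
    length(hoof_set) == 4L, all(hoof_set %in% names),
    length(groups$spine) == 5L, "Neck" %in% groups$spine
  )
  structure(list(names = names, groups = groups, hoof_set = hoof_set),
            class = "cow_skeleton")
}

# Index of a keypoint label in the fixed skeleton order.
kp_index <- function(label, skeleton = cow_skeleton()) {
  i <- match(label, skeleton$names)
  if (anyNA(i)) stop("unknown keypoint label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

#' @export
print.cow_skeleton <- function(x, ...) {
  cat("Cow skeleton: 22 keypoints\n")
  for (g in names(x$groups))
    cat(sprintf("  %-7s %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}
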