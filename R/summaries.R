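# Reduction of strain fields to characteristic regional values and
# segmentation-agreement (Dice) metrics.

#' Characteristic regional strain summary
#'
#' The per-region median element strain is the characteristic value carried
#' into the group statistics; quartiles are reported alongside for box-plot
#' style dispersion. Elements are voxel-sized and therefore equal-volume, so
#' the unweighted median equals the volume-weighted one. Values are reported
#' in percent. Summaries are produced at the region level (zone `"all"`) and
#' additionally per zone for body regions.
#'
#' @param field a [compute_strain_field()] result.
#' @param labeling a [label_regions()] result for the same mesh.
#' @return data.frame with columns `region`, `zone`, `direction`
#'   (`axial`, `circumferential`, `radial`), `median`, `q25`, `q75`
#'   (percent) and `n_elements`. Empty regions are absent, not zero.
#' @export
regional_medians <- function(field, labeling) {
  stopifnot(inherits(field, "strain_field"),
            inherits(labeling, "region_labeling"))
  if (length(labeling$region) != length(field$ezz))
    stop("labeling does not cover the strain field's mesh", call. = FALSE)
  vals <- list(axial = field$ezz, circumferential = field$ett,
               radial = field$err)
  groups <- data.frame(region = labeling$region, zone = labeling$zone,
                       stringsAsFactors = FALSE)
  out <- list()
  emit <- function(sel, region, zone) {
    if (!any(sel)) return(NULL)
    do.call(rbind, lapply(names(vals), function(dir) {
      v <- 100 * vals[[dir]][sel]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      data.frame(region = region, zone = zone, direction = dir,
                 median = q[2], q25 = q[1], q75 = q[3],
                 n_elements = sum(sel), stringsAsFactors = FALSE)
    }))
  }
  for (region in meniscus_regions()) {
    sel <- groups$region == region
    out[[length(out) + 1L]] <- emit(sel, region, "all")
    if (region %in% c("AH", "PI", "PH"))
      for (zone in c("inner", "outer"))
        out[[length(out) + 1L]] <- emit(sel & groups$zone == zone,
                                        region, zone)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dice similarity coefficient of one label
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)` over the voxels carrying `label`
#' in each mask; 1 when both selections are empty.
#'
#' @param a,b congruent [label_mask()]s.
#' @param label the label value to compare (default 1).
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b, label = 1L) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  if (!.same_grid(a, b)) stop("masks are not on the same grid", call. = FALSE)
  A <- a$labels == label; B <- b$labels == label
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Per-region Dice agreement report
#'
#' Compares two regional labelings of the same grid (e.g. two observers'
#' segmentations plus regional division) region by region and for the whole
#' segmentation, annotating each value against the conventional 0.7
#' "excellent agreement" threshold.
#'
#' @param a,b congruent [label_mask()]s whose positive labels encode regions.
#' @param dictionary named integer vector mapping region names to label
#'   values; defaults to the masks' shared dictionary.
#' @param threshold agreement threshold, default 0.7.
#' @return data.frame with columns `region`, `dsc`, `excellent`.
#' @export
dice_report <- function(a, b, dictionary = NULL, threshold = 0.7) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  if (!.same_grid(a, b)) stop("masks are not on the same grid", call. = FALSE)
  if (is.null(dictionary)) dictionary <- a$dictionary
  if (is.null(dictionary)) {
    labs <- sort(setdiff(union(unique(as.vector(a$labels)),
                               unique(as.vector(b$labels))), 0L))
    dictionary <- stats::setNames(labs, paste0("label_", labs))
  }
  if (!is.null(a$dictionary) && !is.null(b$dictionary) &&
      !identical(sort(a$dictionary), sort(b$dictionary)))
    stop("the two masks declare different label dictionaries", call. = FALSE)
  rows <- lapply(names(dictionary), function(nm)
    data.frame(region = nm, dsc = dice(a, b, dictionary[[nm]]),
               stringsAsFactors = FALSE))
  whole <- data.frame(region = "whole",
                      dsc = {
                        A <- a$labels > 0L; B <- b$labels > 0L
                        if (sum(A) + sum(B) == 0L) 1
                        else 2 * sum(A & B) / (sum(A) + sum(B))
                      }, stringsAsFactors = FALSE)
  res <- rbind(do.call(rbind, rows), whole)
  res$excellent <- res$dsc > threshold
  rownames(res) <- NULL
  res
}
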