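#' RI windows defining sperm compartments
#'
#' Three half-open refractive-index intervals `[lo, hi)` partition a sperm
#' tomogram into the whole-cell structure and two sub-compartments. The
#' defaults are the windows used for equine spermatozoa: whole cell
#' 1.348-1.44, post-acrosomal region and midpiece 1.37-1.39, nucleus
#' 1.39-1.44. The shared bound at 1.39 is resolved by the half-open
#' convention in favour of the nucleus, so the two sub-windows are
#' disjoint by construction. Values at or above the whole-window upper
#' bound are left unclassified (reported in the segmentation QC count).
#'
#' @param whole,midpiece,nucleus Numeric `c(lo, hi)` pairs in RI units.
#' @return An object of class `ri_ranges`.
#' @export
ri_ranges <- function(whole = c(1.348, 1.44),
                      midpiece = c(1.37, 1.39),
                      nucleus = c(1.39, 1.44)) {
  win <- list(whole = whole, midpiece = midpiece, nucleus = nucleus)
  for (nm in names(win)) {
    w <- win[[nm]]
    if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
      stop(sprintf("window '%s' must be c(lo, hi) with lo < hi", nm),
           call. = FALSE)
  }
  for (nm in c("midpiece", "nucleus")) {
    w <- win[[nm]]
    if (w[1] < whole[1] || w[2] > whole[2])
      stop(sprintf("window '%s' must lie inside the whole-cell window", nm),
           call. = FALSE)
  }
  if (midpiece[2] > nucleus[1])
    stop("midpiece and nucleus windows must be disjoint (midpiece hi <= nucleus lo)",
         call. = FALSE)
  structure(win, class = "ri_ranges")
}

#' @export
print.ri_ranges <- function(x, ...) {
  cat(sprintf("<ri_ranges> whole [%.3f, %.3f)  midpiece [%.3f, %.3f)  nucleus [%.3f, %.3f)\n",
              x$whole[1], x$whole[2], x$midpiece[1], x$midpiece[2],
              x$nucleus[1], x$nucleus[2]))
  invisible(x)
}

#' Binary region mask aligned to a tomogram
#'
#' @param mask Logical 3D array.
#' @param region Region label (e.g. `"whole"`, `"midpiece"`, `"nucleus"`).
#' @param voxel_size Pitch vector copied from the source tomogram.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, region, voxel_size) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3D array", call. = FALSE)
  structure(list(mask = mask, region = region,
                 voxel_size = as.numeric(voxel_size)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> '%s': %d voxels of %s\n", x$region,
              sum(x$mask), paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' Classify tomogram voxels into RI-window compartments
#'
#' A voxel belongs to region `r` iff `lo_r <= RI < hi_r`; identical windows
#' are applied regardless of the sample's treatment arm. Returns the three
#' raw masks without any cleaning. The number of voxels at or above the
#' whole-window upper bound is attached as attribute `n_unclassified_high`.
#'
#' @param tomogram An [ri_tomogram].
#' @param ranges An [ri_ranges].
#' @return Named list of [region_mask]s (`whole`, `midpiece`, `nucleus`).
#' @export
segment_by_ri <- function(tomogram, ranges = ri_ranges()) {
  stopifnot(inherits(tomogram, "ri_tomogram"), inherits(ranges, "ri_ranges"))
  g <- tomogram$grid
  vs <- tomogram$voxel_size
  res <- cpp_window_masks(g, dim(g),
                          c(ranges$whole[1], ranges$midpiece[1],
                            ranges$nucleus[1]),
                          c(ranges$whole[2], ranges$midpiece[2],
                            ranges$nucleus[2]))
  out <- list(whole = region_mask(res$whole, "whole", vs),
              midpiece = region_mask(res$midpiece, "midpiece", vs),
              nucleus = region_mask(res$nucleus, "nucleus", vs))
  attr(out, "n_unclassified_high") <- res$n_high
  out
}

#' Keep only the largest connected component of a mask
#'
#' Suppresses isolated noise voxels in single-cell fields. Components are
#' found under 26-connectivity by default (6 available). When two
#' components tie in size, the one whose first voxel has the smaller
#' flattened (column-major) index is kept. Empty in, empty out.
#'
#' @param mask A [region_mask].
#' @param connectivity 26 (default) or 6.
#' @return A [region_mask] of the same shape.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "region_mask"))
  if (!connectivity %in% c(6, 26))
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  if (!any(mask$mask)) return(mask)
  m <- cpp_largest_component(mask$mask, dim(mask$mask),
                             as.integer(connectivity))
  region_mask(m, mask$region, mask$voxel_size)
}

#' Segment one sperm cell into clean compartment masks
#'
#' Applies [segment_by_ri()] and then, when `clean = TRUE` (the default for
#' single-cell fields), keeps only the largest connected component of the
#' whole-cell mask and intersects the sub-region masks with it.
#'
#' @inheritParams segment_by_ri
#' @param clean Suppress disconnected noise voxels (default `TRUE`).
#' @param connectivity Passed to [largest_component()].
#' @return Named list of [region_mask]s; attribute `n_unclassified_high`
#'   as in [segment_by_ri()].
#' @export
segment_cell <- function(tomogram, ranges = ri_ranges(), clean = TRUE,
                         connectivity = 26) {
  masks <- segment_by_ri(tomogram, ranges)
  if (clean) {
    whole <- largest_component(masks$whole, connectivity)
    if (!any(whole$mask))
      stop("no cell detected: whole-cell mask is empty after cleaning",
           call. = FALSE)
    qc <- attr(masks, "n_unclassified_high")
    masks$whole <- whole
    for (r in c("midpiece", "nucleus"))
      masks[[r]]$mask <- masks[[r]]$mask & whole$mask
    attr(masks, "n_unclassified_high") <- qc
  } else if (!any(masks$whole$mask)) {
    stop("no cell detected: whole-cell mask is empty", call. = FALSE)
  }
  masks
}

#' Check that phantom compartment RIs sit safely inside their windows
#'
#' Verifies that each compartment RI stays inside its target window with a
#' `3 * noise_sd` guard band (and that the tail and medium stay outside
#' both sub-windows), so additive noise cannot flip voxel labels at any
#' practical rate.
#'
#' @param spec A [phantom_spec].
#' @param ranges An [ri_ranges].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_spec_windows <- function(spec, ranges = ri_ranges()) {
  s3 <- 3 * spec$noise_sd
  inside <- function(v, w) v - s3 >= w[1] && v + s3 < w[2]
  if (!inside(spec$nucleus_ri, ranges$nucleus))
    stop("nucleus RI +/- 3 sd leaves the nucleus window", call. = FALSE)
  if (!inside(spec$midpiece_ri, ranges$midpiece))
    stop("midpiece RI +/- 3 sd leaves the midpiece window", call. = FALSE)
  if (!inside(spec$tail_ri, ranges$whole))
    stop("tail RI +/- 3 sd leaves the whole-cell window", call. = FALSE)
  if (spec$tail_ri + s3 >= ranges$midpiece[1])
    stop("tail RI +/- 3 sd enters a sub-window", call. = FALSE)
  if (spec$medium_ri + s3 >= ranges$whole[1])
    stop("medium RI +/- 3 sd enters the whole-cell window", call. = FALSE)
  invisible(TRUE)
}
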