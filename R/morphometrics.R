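#' Region volume from a voxel mask
#'
#' Volume is the voxel count times the voxel volume; an empty mask has
#' volume 0.
#'
#' @param mask A [region_mask].
#' @param voxel_size Optional pitch override; defaults to the mask's own.
#' @return Volume in um^3.
#' @export
mask_volume <- function(mask, voxel_size = mask$voxel_size) {
  stopifnot(inherits(mask, "region_mask"))
  sum(mask$mask) * voxel_volume(voxel_size)
}

# Gaussian kernel in voxel units, truncated at +/- 3 sd, normalised.
gaussian_kernel <- function(sd_vox) {
  h <- max(1L, ceiling(3 * sd_vox))
  k <- exp(-(seq(-h, h))^2 / (2 * sd_vox^2))
  k / sum(k)
}

# Iso-surface area and enclosed volume of a binary mask. The binary field
# is lightly Gaussian-smoothed before extracting the 0.5 level set by
# marching tetrahedra; smoothing removes the voxelisation staircase that
# otherwise inflates the area of smooth objects. `smooth_sd` is expressed
# in units of the finest voxel pitch and applied isotropically in
# physical space (per-axis sd in voxels = smooth_sd * min(pitch) /
# pitch), so anisotropic grids are not over-smoothed along their coarse
# axis. Structures thinner than the smoothing scale would vanish from
# the 0.5 level set entirely; for those the raw mask is meshed instead.
mask_mesh_stats <- function(mask, voxel_size = mask$voxel_size,
                            smooth_sd = 1) {
  stopifnot(inherits(mask, "region_mask"))
  if (!any(mask$mask))
    stop("surface is undefined for an empty mask", call. = FALSE)
  field <- mask$mask * 1.0
  dim(field) <- dim(mask$mask)
  if (smooth_sd > 0) {
    sd_vox <- smooth_sd * min(voxel_size) / voxel_size
    kernels <- lapply(sd_vox, gaussian_kernel)
    smoothed <- cpp_smooth3(field, dim(field), kernels)
    if (max(smoothed) > 0.5) field <- smoothed
  }
  cpp_mesh_area_volume(field, dim(field), as.numeric(voxel_size), 0.5)
}

#' Region surface area from an iso-surface mesh
#'
#' The binary mask is mildly smoothed and the 0.5 level set extracted as a
#' triangle mesh (marching tetrahedra); the reported area is the mesh
#' area in um^2. Direct voxel-face counting is deliberately avoided: it
#' overestimates smooth surfaces by up to ~50%.
#'
#' The pre-smoothing sd is expressed in units of the finest voxel pitch
#' and applied isotropically in physical space; regions thinner than the
#' smoothing scale fall back to the unsmoothed mesh so they never report
#' a zero surface.
#'
#' @inheritParams mask_volume
#' @param smooth_sd Pre-smoothing Gaussian sd in units of the finest
#'   voxel pitch (0 disables).
#' @return Surface area in um^2.
#' @export
surface_area <- function(mask, voxel_size = mask$voxel_size,
                         smooth_sd = 1) {
  unname(mask_mesh_stats(mask, voxel_size, smooth_sd)["area"])
}

#' Sphericity of a region
#'
#' `pi^(1/3) * (6 V)^(2/3) / A`, the ratio of the surface area of a sphere
#' of equal volume to the actual surface area; 1 for a perfect sphere.
#'
#' @param volume Volume in um^3 (> 0).
#' @param surface_area Surface area in um^2 (> 0).
#' @return Dimensionless sphericity.
#' @export
sphericity <- function(volume, surface_area) {
  if (any(volume <= 0) || any(surface_area <= 0))
    stop("sphericity requires positive volume and surface area",
         call. = FALSE)
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

#' Projection area of a region
#'
#' Area of the maximum-intensity projection of the mask along one axis
#' (default the optical z axis): occupied in-plane pixels times the pixel
#' area.
#'
#' @inheritParams mask_volume
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return Projection area in um^2.
#' @export
projection_area <- function(mask, axis = c("z", "x", "y"),
                            voxel_size = mask$voxel_size) {
  stopifnot(inherits(mask, "region_mask"))
  axis <- match.arg(axis)
  ax <- match(axis, c("x", "y", "z"))
  keep <- setdiff(1:3, ax)
  proj <- apply(mask$mask, keep, any)
  sum(proj) * prod(voxel_size[keep])
}

#' Dry mass of a region
#'
#' The RI excess over the medium maps linearly to dry-matter concentration
#' through the specific refractive increment `alpha` (default 0.185
#' um^3/pg, the standard protein value): mass is the per-voxel
#' concentration `(RI - medium) / alpha` integrated over the mask. Voxels
#' with RI below the medium would contribute negative mass; they are
#' clipped to zero and their count is attached as attribute
#' `n_clipped_negative`.
#'
#' @param tomogram An [ri_tomogram].
#' @param mask A [region_mask] aligned to the tomogram.
#' @param alpha Specific refractive increment in um^3/pg.
#' @return Dry mass in pg (attribute `n_clipped_negative`).
#' @export
dry_mass <- function(tomogram, mask, alpha = 0.185) {
  stopifnot(inherits(tomogram, "ri_tomogram"), inherits(mask, "region_mask"))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!identical(dim(tomogram$grid), dim(mask$mask)))
    stop("tomogram and mask shapes differ", call. = FALSE)
  d <- tomogram$grid[mask$mask] - tomogram$medium_ri
  n_neg <- sum(d < 0)
  d[d < 0] <- 0
  m <- sum(d) / alpha * voxel_volume(tomogram$voxel_size)
  attr(m, "n_clipped_negative") <- n_neg
  m
}

#' Dry-matter concentration of a region
#'
#' @param dry_mass Dry mass in pg.
#' @param volume Region volume in um^3 (> 0).
#' @return Concentration in pg/um^3.
#' @export
ri_concentration <- function(dry_mass, volume) {
  if (any(volume <= 0))
    stop("concentration is undefined for zero volume", call. = FALSE)
  as.numeric(dry_mass) / volume
}

#' Full morphometry of one region
#'
#' Computes the standard holotomography descriptor set for a single
#' region: volume, surface area, sphericity, projection area (optical
#' axis), dry mass, concentration, mean RI and voxel count.
#'
#' @inheritParams dry_mass
#' @param smooth_sd Surface pre-smoothing, see [surface_area()].
#' @return A one-row [tibble::tibble].
#' @export
region_morphometry <- function(tomogram, mask, alpha = 0.185,
                               smooth_sd = 1) {
  vc <- sum(mask$mask)
  vol <- mask_volume(mask)
  if (vc == 0) {
    return(tibble::tibble(region = mask$region, volume = 0,
                          surface_area = NA_real_, sphericity = NA_real_,
                          projection_area = 0, dry_mass = 0,
                          concentration = NA_real_, mean_ri = NA_real_,
                          voxel_count = 0L))
  }
  sa <- surface_area(mask, smooth_sd = smooth_sd)
  dm <- dry_mass(tomogram, mask, alpha)
  tibble::tibble(
    region = mask$region,
    volume = vol,
    surface_area = sa,
    sphericity = sphericity(vol, sa),
    projection_area = projection_area(mask),
    dry_mass = as.numeric(dm),
    concentration = ri_concentration(dm, vol),
    mean_ri = mean(tomogram$grid[mask$mask]),
    voxel_count = vc)
}

#' Morphometry of all compartments of one segmented cell
#'
#' @param tomogram An [ri_tomogram].
#' @param masks Named list of [region_mask]s, e.g. from [segment_cell()].
#' @inheritParams region_morphometry
#' @return A [tibble::tibble], one row per region.
#' @export
cell_morphometry <- function(tomogram, masks, alpha = 0.185,
                             smooth_sd = 1) {
  dplyr::bind_rows(lapply(masks, region_morphometry, tomogram = tomogram,
                          alpha = alpha, smooth_sd = smooth_sd))
}

#' Run the segmentation + morphometry pipeline over a simulated study
#'
#' Renders each cell of an [simulate_study()] cohort, segments it with the
#' RI windows and measures each compartment. With
#' `measures = "volume"` (the default) only volumes are computed, which is
#' what the freezability index needs and keeps large cohorts fast; with
#' `measures = "full"` the complete descriptor set of
#' [region_morphometry()] is returned.
#'
#' @param study An `ht_study`.
#' @param ranges An [ri_ranges].
#' @param clean Passed to [segment_cell()].
#' @param measures `"volume"` or `"full"`.
#' @param alpha Specific refractive increment for dry mass.
#' @return A [tibble::tibble] with one row per cell x region.
#' @export
study_morphometry <- function(study, ranges = ri_ranges(), clean = TRUE,
                              measures = c("volume", "full"),
                              alpha = 0.185) {
  stopifnot(inherits(study, "ht_study"))
  measures <- match.arg(measures)
  n <- nrow(study$cells)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    tom <- if (!is.null(study$tomograms)) study$tomograms[[i]]
           else render_study_cell(study, i)
    masks <- segment_cell(tom, ranges, clean = clean)
    row <- study$cells[i, ]
    if (measures == "volume") {
      tab <- tibble::tibble(
        region = names(masks),
        volume = vapply(masks, mask_volume, 0))
    } else {
      tab <- cell_morphometry(tom, masks, alpha = alpha)
    }
    res[[i]] <- dplyr::mutate(tab, donor = row$donor,
                              extender = row$extender,
                              cell_id = row$cell_id, .before = 1)
  }
  dplyr::bind_rows(res)
}
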