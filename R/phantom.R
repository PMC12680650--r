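#' Synthetic sperm phantom specification
#'
#' Describes a simplified three-compartment spermatozoon used to exercise
#' the tomographic pipeline: an ellipsoidal nucleus, a cylindrical midpiece
#' abutting the nucleus along the +x axis and a thinner cylindrical tail.
#' Compartment RI values default to the centres of the segmentation windows
#' (nucleus 1.415, midpiece 1.380) with the tail at 1.360, inside the
#' whole-cell window but outside both sub-windows; the medium defaults to a
#' PBS-like 1.337. Geometry is a reduced-scale schematic sized to fit a
#' 64^3 grid at the default pitch, not a full-length spermatozoon.
#'
#' At render time a short "neck" at tail RI bridges the nucleus tip and the
#' midpiece cylinder (see [render_tomogram()]): it keeps the whole-cell
#' mask voxel-connected without entering either sub-window, so the
#' midpiece RI window measures the bare cylinder `pi * r^2 * length`.
#'
#' @param nucleus_semiaxes Ellipsoid semi-axes `(a, b, c)` in um; `a` lies
#'   along the cell's long axis.
#' @param nucleus_ri,midpiece_ri,tail_ri,medium_ri Compartment RI values.
#' @param midpiece_length,midpiece_radius,tail_length,tail_radius
#'   Cylinder dimensions in um.
#' @param noise_sd Standard deviation of additive Gaussian RI noise.
#' @param shrinkage Named region -> factor map recording cumulative volume
#'   scaling already applied (see [apply_cryo_effect()]).
#' @param seed Optional integer seed used by [render_tomogram()] for noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nucleus_semiaxes = c(1.1, 0.8, 0.45),
                         nucleus_ri = 1.415,
                         midpiece_length = 1.8, midpiece_radius = 0.35,
                         midpiece_ri = 1.380,
                         tail_length = 1.8, tail_radius = 0.20,
                         tail_ri = 1.360,
                         medium_ri = 1.337,
                         noise_sd = 0.002,
                         shrinkage = c(nucleus = 1, midpiece = 1, tail = 1),
                         seed = NULL) {
  geom <- c(nucleus_semiaxes, midpiece_length, midpiece_radius,
            tail_length, tail_radius)
  if (any(geom <= 0)) stop("all geometric parameters must be > 0",
                           call. = FALSE)
  if (length(nucleus_semiaxes) != 3L)
    stop("`nucleus_semiaxes` must have length 3", call. = FALSE)
  if (!(medium_ri < midpiece_ri && midpiece_ri < nucleus_ri))
    stop("require medium_ri < midpiece_ri < nucleus_ri", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  shr <- c(nucleus = 1, midpiece = 1, tail = 1)
  shr[names(shrinkage)] <- shrinkage
  if (any(shr <= 0) || any(shr > 1.5))
    stop("shrinkage factors must lie in (0, 1.5]", call. = FALSE)
  structure(
    list(nucleus_semiaxes = as.numeric(nucleus_semiaxes),
         nucleus_ri = nucleus_ri,
         midpiece_length = midpiece_length,
         midpiece_radius = midpiece_radius, midpiece_ri = midpiece_ri,
         tail_length = tail_length, tail_radius = tail_radius,
         tail_ri = tail_ri, medium_ri = medium_ri, noise_sd = noise_sd,
         shrinkage = shr, seed = seed),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> nucleus (%.2f, %.2f, %.2f) um @ RI %.3f; ",
                     "midpiece L %.2f r %.2f @ %.3f; tail L %.2f r %.2f @ %.3f\n"),
              x$nucleus_semiaxes[1], x$nucleus_semiaxes[2],
              x$nucleus_semiaxes[3], x$nucleus_ri, x$midpiece_length,
              x$midpiece_radius, x$midpiece_ri, x$tail_length,
              x$tail_radius, x$tail_ri))
  cat(sprintf("  medium RI %.3f, noise sd %.4f, shrinkage n/m/t %.2f/%.2f/%.2f\n",
              x$medium_ri, x$noise_sd, x$shrinkage["nucleus"],
              x$shrinkage["midpiece"], x$shrinkage["tail"]))
  invisible(x)
}

#' Analytic (ground-truth) compartment volumes of a phantom, in um^3
#'
#' Nucleus: ellipsoid `4/3 pi a b c`; midpiece and tail: cylinders
#' `pi r^2 L`. The rendered neck bridging nucleus and midpiece is not
#' included: it only contributes to the whole-cell window, by about 1% at
#' the default geometry, and cancels in frozen/fresh volume ratios.
#'
#' @param spec A [phantom_spec].
#' @return Named numeric vector `nucleus, midpiece, tail, whole`.
#' @export
phantom_true_volumes <- function(spec) {
  nuc <- 4 / 3 * pi * prod(spec$nucleus_semiaxes)
  mid <- pi * spec$midpiece_radius^2 * spec$midpiece_length
  tail <- pi * spec$tail_radius^2 * spec$tail_length
  c(nucleus = nuc, midpiece = mid, tail = tail, whole = nuc + mid + tail)
}

# Physical extent of the phantom along each axis, in um.
phantom_extent <- function(spec) {
  a <- spec$nucleus_semiaxes[1]
  len_x <- 2 * a + spec$midpiece_length + spec$tail_length
  half_yz <- max(spec$nucleus_semiaxes[2:3], spec$midpiece_radius,
                 spec$tail_radius)
  c(x = len_x, y = 2 * half_yz, z = 2 * half_yz)
}

#' Apply a cryopreservation volume effect to a phantom
#'
#' Cryopreservation-induced dehydration is modelled as an isotropic volume
#' change per compartment: a region with factor `f` has each linear
#' dimension scaled by `f^(1/3)`, so its volume scales by exactly `f`.
#' Factors above 1 model swelling. The input spec is unchanged; the
#' returned spec records the cumulative factors in `$shrinkage`.
#'
#' @param spec A [phantom_spec].
#' @param shrinkage Named numeric vector with any of `nucleus`, `midpiece`,
#'   `tail`; missing regions keep factor 1.
#' @return A new [phantom_spec].
#' @export
apply_cryo_effect <- function(spec, shrinkage) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- c(nucleus = 1, midpiece = 1, tail = 1)
  if (is.null(names(shrinkage)) ||
      !all(names(shrinkage) %in% names(f)))
    stop("`shrinkage` must be named with regions in nucleus/midpiece/tail",
         call. = FALSE)
  f[names(shrinkage)] <- shrinkage
  if (any(!is.finite(f)) || any(f <= 0))
    stop("shrinkage factors must be positive", call. = FALSE)
  lin <- f^(1 / 3)
  out <- spec
  out$nucleus_semiaxes <- spec$nucleus_semiaxes * unname(lin["nucleus"])
  out$midpiece_length <- spec$midpiece_length * unname(lin["midpiece"])
  out$midpiece_radius <- spec$midpiece_radius * unname(lin["midpiece"])
  out$tail_length <- spec$tail_length * unname(lin["tail"])
  out$tail_radius <- spec$tail_radius * unname(lin["tail"])
  out$shrinkage <- spec$shrinkage * f
  out
}

#' Render a phantom into an RI tomogram
#'
#' Fills a voxel grid with the medium RI, overwrites compartment voxels
#' (nucleus takes precedence over the midpiece in their overlap region)
#' and adds i.i.d. Gaussian RI noise of sd `spec$noise_sd`. Rendering is
#' deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec].
#' @param voxel_size Pitch `(dx, dy, dz)` in um. The default matches the
#'   instrument-class lateral/axial resolution of 110/220 nm.
#' @param grid_shape Grid size `(nx, ny, nz)`.
#' @param center Optional nucleus centre `(cx, cy, cz)` in um; defaults to
#'   centring the whole assembly in the grid.
#' @param seed Seed for the noise; defaults to `spec$seed`. `NULL` uses the
#'   current RNG state.
#' @param junction_overlap_voxels Length, in voxel columns, of the neck
#'   rendered at tail RI between the nucleus tip and the midpiece
#'   cylinder. The neck keeps the whole-cell mask voxel-connected across
#'   the junction; because it carries tail RI it never enters the
#'   midpiece or nucleus windows.
#' @return An [ri_tomogram].
#' @export
render_tomogram <- function(spec, voxel_size = c(0.11, 0.11, 0.22),
                            grid_shape = c(64, 64, 64), center = NULL,
                            seed = spec$seed,
                            junction_overlap_voxels = 1.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(voxel_size <= 0))
    stop("voxel sizes must be positive", call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  ext_phys <- grid_shape * voxel_size
  ext <- phantom_extent(spec)
  if (is.null(center)) {
    a <- spec$nucleus_semiaxes[1]
    cx <- (ext_phys[1] - ext["x"]) / 2 + a
    center <- c(cx, ext_phys[2] / 2, ext_phys[3] / 2)
  }
  a <- spec$nucleus_semiaxes[1]
  lo <- c(center[1] - a,
          center[2] - ext["y"] / 2,
          center[3] - ext["z"] / 2)
  hi <- c(center[1] + a + spec$midpiece_length + spec$tail_length,
          center[2] + ext["y"] / 2,
          center[3] + ext["z"] / 2)
  margin <- 2 * voxel_size
  if (any(lo < margin) || any(hi > ext_phys - margin))
    stop("phantom does not fit inside the grid with a 2-voxel margin",
         call. = FALSE)
  render <- function() {
    cpp_render_phantom(grid_shape, as.numeric(voxel_size),
                       as.numeric(center),
                       spec$nucleus_semiaxes[1], spec$nucleus_semiaxes[2],
                       spec$nucleus_semiaxes[3], spec$nucleus_ri,
                       spec$midpiece_length, spec$midpiece_radius,
                       spec$midpiece_ri,
                       junction_overlap_voxels * voxel_size[1],
                       spec$tail_length, spec$tail_radius, spec$tail_ri,
                       spec$medium_ri, spec$noise_sd)
  }
  g <- if (spec$noise_sd > 0 && !is.null(seed)) {
    withr::with_seed(seed, render())
  } else {
    render()
  }
  ri_tomogram(g, voxel_size, spec$medium_ri,
              metadata = list(seed = seed))
}

#' Donor-by-extender study design for synthetic cohorts
#'
#' Encodes the cohort structure of a cryotolerance study: `n_donors`
#' donors, one fresh-reference extender plus freezing extenders, and
#' `cells_per_sample` cells imaged per donor x extender sample. Donor
#' baseline size effects are log-normal volume scalings; each freezing
#' extender has a per-region Gaussian distribution of volume shrinkage
#' factors. A donor's `susceptibility` attenuates shrinkage towards 1
#' (susceptibility 0 = perfectly cryotolerant "good cooler").
#'
#' Defaults emulate an 11-stallion study with four freezing extenders in
#' which the midpiece is the most affected compartment (mean factors down
#' to ~0.55, i.e. more than 50% loss for part of the cohort), the nucleus
#' is nearly stable, and donors 2 and 4 are good coolers.
#'
#' @param n_donors Number of donors.
#' @param extenders Character vector of extender labels; the first element
#'   of `fresh_label` must appear in it.
#' @param fresh_label Label of the fresh (non-frozen) reference extender.
#' @param cells_per_sample Cells imaged per donor x extender.
#' @param donor_sd Log-scale SD of the donor baseline volume effect.
#' @param extender_effects Named list, one element per freezing extender,
#'   each a list of `mean` and `sd` named region vectors for the shrinkage
#'   factor distribution.
#' @param good_coolers Integer donor indices with low susceptibility.
#' @param good_cooler_susceptibility Susceptibility of good coolers.
#' @param seed Integer seed fixing donor effects and all downstream draws.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_donors = 11,
                         extenders = c("INRA96", "SpectrumDuoRed",
                                       "BotuCrio", "INRAFreeze", "HF20"),
                         fresh_label = "INRA96",
                         cells_per_sample = 40,
                         donor_sd = 0.10,
                         extender_effects = NULL,
                         good_coolers = c(2, 4),
                         good_cooler_susceptibility = 0.1,
                         seed = 1L) {
  if (n_donors < 1 || cells_per_sample < 1)
    stop("need at least one donor and one cell per sample", call. = FALSE)
  if (!fresh_label %in% extenders)
    stop("`fresh_label` must be one of `extenders`", call. = FALSE)
  frozen <- setdiff(extenders, fresh_label)
  if (length(frozen) < 1)
    stop("need at least one freezing extender besides the fresh reference",
         call. = FALSE)
  if (is.null(extender_effects)) {
    eff <- list(
      SpectrumDuoRed = list(mean = c(nucleus = 0.97, midpiece = 0.72, tail = 0.82),
                            sd = c(nucleus = 0.03, midpiece = 0.08, tail = 0.08)),
      BotuCrio = list(mean = c(nucleus = 0.98, midpiece = 0.78, tail = 0.86),
                      sd = c(nucleus = 0.03, midpiece = 0.08, tail = 0.08)),
      INRAFreeze = list(mean = c(nucleus = 0.96, midpiece = 0.66, tail = 0.80),
                        sd = c(nucleus = 0.03, midpiece = 0.08, tail = 0.08)),
      HF20 = list(mean = c(nucleus = 0.95, midpiece = 0.55, tail = 0.75),
                  sd = c(nucleus = 0.03, midpiece = 0.10, tail = 0.08)))
    extender_effects <- eff[intersect(names(eff), frozen)]
    # any non-default frozen extender label gets a generic moderate effect
    for (x in setdiff(frozen, names(extender_effects)))
      extender_effects[[x]] <-
        list(mean = c(nucleus = 0.96, midpiece = 0.70, tail = 0.80),
             sd = c(nucleus = 0.03, midpiece = 0.08, tail = 0.08))
    extender_effects <- extender_effects[frozen]
  }
  if (!setequal(names(extender_effects), frozen))
    stop("`extender_effects` must name exactly the freezing extenders",
         call. = FALSE)
  for (x in frozen) {
    m <- extender_effects[[x]]$mean
    if (any(m <= 0)) stop("extender effect means must be > 0", call. = FALSE)
  }
  susceptibility <- rep(1, n_donors)
  good_coolers <- good_coolers[good_coolers <= n_donors]
  susceptibility[good_coolers] <- good_cooler_susceptibility
  donor_effects <- withr::with_seed(seed,
                                    rlnorm(n_donors, 0, donor_sd))
  structure(
    list(n_donors = n_donors, extenders = extenders,
         fresh_label = fresh_label, cells_per_sample = cells_per_sample,
         donor_effects = donor_effects, susceptibility = susceptibility,
         extender_effects = extender_effects, seed = as.integer(seed)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d donors x %d extenders (fresh: %s) x %d cells\n",
              x$n_donors, length(x$extenders), x$fresh_label,
              x$cells_per_sample))
  invisible(x)
}

#' Simulate a synthetic holotomography cohort
#'
#' Draws one phantom per donor x extender x cell. Each donor has a fresh
#' baseline phantom (the base spec scaled by the donor's baseline volume
#' effect); cells under a freezing extender take that baseline through
#' [apply_cryo_effect()] with region shrinkage factors drawn from the
#' extender's distribution, attenuated by the donor's susceptibility
#' (`f_eff = 1 - s * (1 - f)`). Per-cell sub-voxel centre jitter decorrelates
#' voxelisation error across cells. Fully reproducible from `design$seed`.
#'
#' @param design A [study_design].
#' @param base_spec Fresh-reference [phantom_spec] before donor scaling.
#' @param voxel_size,grid_shape Rendering geometry (see [render_tomogram()]).
#' @param render If `TRUE`, the returned object carries the rendered
#'   tomograms in `$tomograms` (memory-heavy for large designs); if
#'   `FALSE`, render cells on demand with [render_study_cell()].
#' @return An object of class `ht_study` with `$cells` (one row per cell:
#'   donor, extender, cell_id, per-region true shrinkage factors, jitter,
#'   noise seed, spec in a list-column), `$truth` (long ground-truth table
#'   donor, extender, cell_id, region, true_volume_um3) and optionally
#'   `$tomograms`.
#' @export
simulate_study <- function(design, base_spec = phantom_spec(),
                           voxel_size = c(0.11, 0.11, 0.22),
                           grid_shape = c(64, 64, 64),
                           render = FALSE) {
  stopifnot(inherits(design, "study_design"),
            inherits(base_spec, "phantom_spec"))
  rows <- withr::with_seed(child_seed(design$seed, 1), {
    out <- list()
    n <- 0L
    for (d in seq_len(design$n_donors)) {
      donor_spec <- scale_spec_volume(base_spec, design$donor_effects[d])
      for (ext in design$extenders) {
        for (cell in seq_len(design$cells_per_sample)) {
          if (ext == design$fresh_label) {
            f <- c(nucleus = 1, midpiece = 1, tail = 1)
          } else {
            e <- design$extender_effects[[ext]]
            raw <- rnorm(3, e$mean[c("nucleus", "midpiece", "tail")],
                         e$sd[c("nucleus", "midpiece", "tail")])
            raw <- pmin(pmax(raw, 0.05), 1.5)
            f <- 1 - design$susceptibility[d] * (1 - raw)
            names(f) <- c("nucleus", "midpiece", "tail")
          }
          spec <- apply_cryo_effect(donor_spec, f)
          jit <- runif(3, -0.5, 0.5) * voxel_size
          noise_seed <- sample.int(.Machine$integer.max, 1L)
          n <- n + 1L
          out[[n]] <- list(donor = d, extender = ext, cell_id = cell,
                           f_nucleus = unname(f["nucleus"]),
                           f_midpiece = unname(f["midpiece"]),
                           f_tail = unname(f["tail"]),
                           jitter = jit, noise_seed = noise_seed,
                           spec = spec)
        }
      }
    }
    out
  })
  cells <- tibble::tibble(
    donor = vapply(rows, `[[`, 0, "donor"),
    extender = vapply(rows, `[[`, "", "extender"),
    cell_id = vapply(rows, `[[`, 0, "cell_id"),
    f_nucleus = vapply(rows, `[[`, 0, "f_nucleus"),
    f_midpiece = vapply(rows, `[[`, 0, "f_midpiece"),
    f_tail = vapply(rows, `[[`, 0, "f_tail"),
    jitter = lapply(rows, `[[`, "jitter"),
    noise_seed = vapply(rows, `[[`, 0, "noise_seed"),
    spec = lapply(rows, `[[`, "spec"))
  truth <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- phantom_true_volumes(cells$spec[[i]])
    data.frame(donor = cells$donor[i], extender = cells$extender[i],
               cell_id = cells$cell_id[i], region = names(v),
               true_volume_um3 = unname(v))
  }))
  study <- structure(
    list(cells = cells, truth = tibble::as_tibble(truth),
         design = design, voxel_size = as.numeric(voxel_size),
         grid_shape = as.integer(grid_shape), tomograms = NULL),
    class = "ht_study")
  if (render)
    study$tomograms <- lapply(seq_len(nrow(cells)), render_study_cell,
                              study = study)
  study
}

# Derive a reproducible child seed without 32-bit integer overflow.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% 2147483647)
}

# Scale every compartment's volume by `factor` (linear dims by factor^(1/3)).
scale_spec_volume <- function(spec, factor) {
  stopifnot(factor > 0)
  lin <- factor^(1 / 3)
  out <- spec
  out$nucleus_semiaxes <- spec$nucleus_semiaxes * lin
  out$midpiece_length <- spec$midpiece_length * lin
  out$midpiece_radius <- spec$midpiece_radius * lin
  out$tail_length <- spec$tail_length * lin
  out$tail_radius <- spec$tail_radius * lin
  out
}

#' Render one cell of a simulated study
#'
#' @param study An `ht_study` from [simulate_study()].
#' @param i Row index into `study$cells`.
#' @return An [ri_tomogram] with donor/extender/cell metadata.
#' @export
render_study_cell <- function(study, i) {
  stopifnot(inherits(study, "ht_study"))
  row <- study$cells[i, ]
  spec <- row$spec[[1]]
  ext_phys <- study$grid_shape * study$voxel_size
  ext <- phantom_extent(spec)
  a <- spec$nucleus_semiaxes[1]
  center <- c((ext_phys[1] - ext["x"]) / 2 + a,
              ext_phys[2] / 2, ext_phys[3] / 2) + row$jitter[[1]]
  tom <- render_tomogram(spec, study$voxel_size, study$grid_shape,
                         center = center, seed = row$noise_seed)
  tom$metadata <- list(donor = row$donor, extender = row$extender,
                       cell_id = row$cell_id, seed = row$noise_seed)
  tom
}

#' @export
print.ht_study <- function(x, ...) {
  cat(sprintf("<ht_study> %d cells (%d donors x %d extenders x %d cells), grid %s\n",
              nrow(x$cells), x$design$n_donors, length(x$design$extenders),
              x$design$cells_per_sample,
              paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Each cell becomes a TIFF stack plus JSON sidecar
#' (`donorD_EXT_cellC.tif/.json`); the ground truth goes to
#' `ground_truth.csv` with columns donor, extender, cell_id, region,
#' true_volume_um3.
#'
#' @param study An `ht_study`.
#' @param dir Output directory (created if missing).
#' @param cells Optional row indices to write (default: all).
#' @return Paths of the TIFF files, invisibly.
#' @export
write_study <- function(study, dir, cells = seq_len(nrow(study$cells))) {
  stopifnot(inherits(study, "ht_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in cells) {
    tom <- if (!is.null(study$tomograms)) study$tomograms[[i]]
           else render_study_cell(study, i)
    row <- study$cells[i, ]
    p <- file.path(dir, sprintf("donor%02d_%s_cell%03d.tif",
                                row$donor, row$extender, row$cell_id))
    write_tomogram(tom, p)
    paths <- c(paths, p)
  }
  readr::write_csv(study$truth, file.path(dir, "ground_truth.csv"))
  invisible(paths)
}
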