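#' Refractive-index tomogram container
#'
#' An `ri_tomogram` bundles a 3D grid of refractive-index (RI) values with
#' its voxel geometry and the RI of the surrounding medium. The grid is a
#' numeric array with `dim = c(nx, ny, nz)`; `z` is the optical axis.
#' Physical coordinates are in micrometres with the origin at the grid
#' corner and voxel centres at `(i + 0.5) * pitch` (0-based `i`).
#'
#' @param grid Numeric 3D array of RI values (dimensionless, all >= 1).
#' @param voxel_size Numeric length-3 vector `(dx, dy, dz)` in micrometres.
#' @param medium_ri RI of the mounting medium.
#' @param metadata Optional named list carried along (donor, extender, ...).
#' @return An object of class `ri_tomogram`.
#' @export
ri_tomogram <- function(grid, voxel_size, medium_ri, metadata = list()) {
  if (!is.array(grid) || length(dim(grid)) != 3L || length(grid) == 0L)
    stop("`grid` must be a non-empty 3D array", call. = FALSE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive pitches (dx, dy, dz) in um",
         call. = FALSE)
  if (anyNA(grid)) stop("`grid` contains NA values", call. = FALSE)
  bad <- which(grid < 1.0)
  if (length(bad))
    stop(sprintf("RI < 1.0 encountered at voxel index %d (value %.4f)",
                 bad[1], grid[bad[1]]), call. = FALSE)
  structure(
    list(grid = grid, voxel_size = as.numeric(voxel_size),
         medium_ri = medium_ri, metadata = metadata),
    class = "ri_tomogram")
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<ri_tomogram> %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  RI range [%.4f, %.4f], medium %.4f\n",
              min(x$grid), max(x$grid), x$medium_ri))
  invisible(x)
}

#' Voxel volume of a tomogram or mask, in cubic micrometres
#' @param voxel_size Length-3 pitch vector in micrometres.
#' @export
voxel_volume <- function(voxel_size) prod(voxel_size)

# Sidecar path next to a TIFF stack.
sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

# TIFF samples must sit in [0, 1]; RI values are stored shifted by this
# offset (RI - offset), which keeps sperm-range RI well inside [0, 1].
RI_TIFF_OFFSET <- 1.0

#' Write a tomogram as a 3D TIFF stack plus JSON sidecar
#'
#' One single-channel 32-bit TIFF holds the z-slices; the sidecar carries
#' `voxel_size_um` (dx, dy, dz), `medium_ri`, the storage offset and any
#' metadata. Stored sample precision is ~1e-9 in RI, i.e. beyond
#' single-precision float.
#'
#' @param tomogram An [ri_tomogram].
#' @param path Output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomogram, path) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  g <- tomogram$grid
  nz <- dim(g)[3]
  # slice k as a matrix with rows = y, cols = x
  slices <- lapply(seq_len(nz), function(k) t(g[, , k]) - RI_TIFF_OFFSET)
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- c(list(voxel_size_um = tomogram$voxel_size,
                 medium_ri = tomogram$medium_ri,
                 ri_offset = RI_TIFF_OFFSET),
            tomogram$metadata)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a tomogram written by [write_tomogram()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it.
#' @return An [ri_tomogram].
#' @export
read_tomogram <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(path)) stop("tomogram file not found: ", path, call. = FALSE)
  if (!file.exists(sp))
    stop("missing JSON sidecar for tomogram: ", sp, call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (key in c("voxel_size_um", "medium_ri")) {
    if (is.null(side[[key]]))
      stop(sprintf("tomogram sidecar %s lacks required key '%s'", sp, key),
           call. = FALSE)
  }
  offset <- if (is.null(side$ri_offset)) RI_TIFF_OFFSET else side$ri_offset
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  g <- vapply(slices, function(s) t(s) + offset,
              matrix(0, ncol(slices[[1]]), nrow(slices[[1]])))
  meta <- side[setdiff(names(side), c("voxel_size_um", "medium_ri",
                                      "ri_offset"))]
  ri_tomogram(g, side$voxel_size_um, side$medium_ri, metadata = meta)
}

#' Write / read a binary region mask as an 8-bit TIFF
#'
#' Foreground voxels are stored as 255, background as 0.
#'
#' @param mask A [region_mask].
#' @param path TIFF path.
#' @return `path` invisibly (write) or a [region_mask] (read).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  g <- mask$mask
  slices <- lapply(seq_len(dim(g)[3]), function(k) t(g[, , k]) * 1.0)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  side <- list(voxel_size_um = mask$voxel_size, region = mask$region)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar for mask: ", sp,
                             call. = FALSE)
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  g <- vapply(slices, function(s) t(s) > 0.5,
              matrix(TRUE, ncol(slices[[1]]), nrow(slices[[1]])))
  region_mask(g, side$region, side$voxel_size_um)
}

#' Write sperm tracks to CSV
#'
#' Long format with columns `track_id, frame, x_um, y_um` and the frame
#' rate recorded in a `# fps=` header line.
#'
#' @param tracks List of [sperm_track] objects sharing one frame rate.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(length(tracks) > 0, all(vapply(tracks, inherits, TRUE,
                                           "sperm_track")))
  fps <- unique(vapply(tracks, function(t) t$fps, 0))
  if (length(fps) != 1L)
    stop("all tracks in one file must share the frame rate", call. = FALSE)
  tab <- dplyr::bind_rows(lapply(tracks, function(t) {
    tibble::tibble(track_id = t$track_id,
                   frame = seq_len(nrow(t$positions)) - 1L,
                   x_um = t$positions[, 1], y_um = t$positions[, 2])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%.10g", fps), con)
  utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sperm tracks from CSV
#'
#' Expects columns `track_id, frame, x_um, y_um`. The frame rate is taken
#' from a `# fps=` header line unless supplied. Frames within a track must
#' be strictly increasing and gap-free; violations are hard errors rather
#' than silent drops.
#'
#' @param path CSV path.
#' @param fps Frames per second; overrides the file header if given.
#' @return A list of [sperm_track] objects, in file order.
#' @export
read_tracks <- function(path, fps = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*fps\\s*=", first)) {
    file_fps <- as.numeric(sub("^#\\s*fps\\s*=\\s*", "", first))
    if (is.null(fps)) fps <- file_fps
  }
  if (is.null(fps) || !is.finite(fps) || fps <= 0)
    stop("frame rate not found in header and no valid `fps` supplied",
         call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("track CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ids <- unique(tab$track_id)
  tracks <- lapply(ids, function(id) {
    sub <- tab[tab$track_id == id, , drop = FALSE]
    fr <- sub$frame
    if (anyDuplicated(fr))
      stop(sprintf("track '%s' has duplicated frame numbers", id),
           call. = FALSE)
    if (is.unsorted(fr, strictly = TRUE))
      stop(sprintf("track '%s' has non-monotonic frame numbers", id),
           call. = FALSE)
    if (!all(diff(fr) == 1L))
      stop(sprintf("track '%s' has missing frames (gaps)", id),
           call. = FALSE)
    sperm_track(sub$x_um, sub$y_um, fps = fps, track_id = id)
  })
  if (length(tracks) != length(ids))
    stop("internal error: track count mismatch", call. = FALSE)
  tracks
}
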