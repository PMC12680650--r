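#' A single sperm track
#'
#' A time-ordered sequence of 2D positions sampled at a uniform frame
#' rate, as exported by CASA systems.
#'
#' @param x,y Position coordinates in micrometres (same length, >= 2).
#' @param fps Frames per second (> 0).
#' @param track_id Identifier carried through summaries.
#' @return An object of class `sperm_track`.
#' @export
sperm_track <- function(x, y, fps, track_id = NA) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("a track needs >= 2 (x, y) points of equal length", call. = FALSE)
  if (!is.finite(fps) || fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("track positions contain NA", call. = FALSE)
  structure(list(positions = cbind(x_um = as.numeric(x),
                                   y_um = as.numeric(y)),
                 fps = fps, track_id = track_id),
            class = "sperm_track")
}

#' @export
print.sperm_track <- function(x, ...) {
  cat(sprintf("<sperm_track> '%s': %d frames @ %g fps\n", x$track_id,
              nrow(x$positions), x$fps))
  invisible(x)
}

track_duration <- function(track) (nrow(track$positions) - 1) / track$fps

path_length <- function(pos) {
  d <- diff(pos)
  sum(sqrt(rowSums(d^2)))
}

#' Curvilinear velocity (VCL)
#'
#' Total point-to-point path length divided by track duration, in um/s.
#'
#' @param track A [sperm_track].
#' @return VCL in um/s.
#' @export
vcl <- function(track) {
  stopifnot(inherits(track, "sperm_track"))
  path_length(track$positions) / track_duration(track)
}

#' Straight-line velocity (VSL)
#'
#' Distance between the first and last track point divided by duration.
#'
#' @inheritParams vcl
#' @return VSL in um/s.
#' @export
vsl <- function(track) {
  stopifnot(inherits(track, "sperm_track"))
  p <- track$positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2)) / track_duration(track)
}

# Centred moving average whose half-width shrinks symmetrically near the
# track ends (so the first and last smoothed points equal the raw
# endpoints, and collinear tracks stay collinear end to end).
smooth_positions <- function(pos, window) {
  if (window %% 2 != 1 || window < 1)
    stop("smoothing `window` must be odd and >= 1", call. = FALSE)
  if (window == 1) return(pos)
  h <- (window - 1) %/% 2
  n <- nrow(pos)
  out <- pos
  for (i in seq_len(n)) {
    hi_i <- min(h, i - 1L, n - i)
    if (hi_i > 0)
      out[i, ] <- colMeans(pos[(i - hi_i):(i + hi_i), , drop = FALSE])
  }
  out
}

#' Average-path velocity (VAP)
#'
#' Length of the moving-average-smoothed path divided by duration. The
#' smoother is a centred mean over `window` frames (default 5) that
#' shrinks symmetrically at the track ends.
#'
#' @inheritParams vcl
#' @param window Odd smoothing window in frames.
#' @return VAP in um/s.
#' @export
vap <- function(track, window = 5) {
  stopifnot(inherits(track, "sperm_track"))
  sm <- smooth_positions(track$positions, window)
  path_length(sm) / track_duration(track)
}

#' Track straightness (STR)
#'
#' `VSL / VAP * 100` (percent). Returns `NA` when VAP is 0 (the track is
#' then treated as immotile by [classify_track()]).
#'
#' @inheritParams vap
#' @return STR in percent, or `NA` for a degenerate track.
#' @export
straightness <- function(track, window = 5) {
  v <- vap(track, window)
  if (v == 0) return(NA_real_)
  vsl(track) / v * 100
}

#' Default CASA motility thresholds
#'
#' Tracks with average (path) velocity below `immotile_vap` um/s are
#' immotile; progressive tracks need VAP above `progressive_vap` um/s and
#' straightness above `progressive_str` percent.
#'
#' @param immotile_vap,progressive_vap Velocity cut-offs in um/s.
#' @param progressive_str Straightness cut-off in percent.
#' @export
motility_thresholds <- function(immotile_vap = 10, progressive_vap = 30,
                                progressive_str = 80) {
  list(immotile_vap = immotile_vap, progressive_vap = progressive_vap,
       progressive_str = progressive_str)
}

#' Classify a track as immotile, motile or progressive
#'
#' The "average velocity" in the immotility rule is read as VAP (the CASA
#' convention); switch to VCL with `velocity = "vcl"`. Progressive implies
#' motile.
#'
#' @inheritParams vap
#' @param thresholds A [motility_thresholds()] list.
#' @param velocity Which velocity drives the immotility rule.
#' @return One of `"immotile"`, `"motile"`, `"progressive"`.
#' @export
classify_track <- function(track, thresholds = motility_thresholds(),
                           window = 5, velocity = c("vap", "vcl")) {
  velocity <- match.arg(velocity)
  v_ap <- vap(track, window)
  v_ref <- if (velocity == "vap") v_ap else vcl(track)
  if (!is.finite(v_ref) || v_ref < thresholds$immotile_vap ||
      v_ap == 0) return("immotile")
  str <- vsl(track) / v_ap * 100
  if (v_ap > thresholds$progressive_vap &&
      str > thresholds$progressive_str) "progressive" else "motile"
}

#' Population kinematic summary
#'
#' Total motility (TM) is the percentage of non-immotile tracks,
#' progressive motility (PM) the percentage of progressive tracks;
#' velocity means are taken over motile (non-immotile) tracks, or are `NA`
#' when every track is immotile.
#'
#' @param tracks Non-empty list of [sperm_track]s.
#' @inheritParams classify_track
#' @return A one-row [tibble::tibble] with TM, PM, mean VCL/VSL/VAP and
#'   `n_tracks`.
#' @export
summarize_tracks <- function(tracks, thresholds = motility_thresholds(),
                             window = 5, velocity = "vap") {
  if (length(tracks) == 0)
    stop("cannot summarise an empty track list", call. = FALSE)
  cls <- vapply(tracks, classify_track, "", thresholds = thresholds,
                window = window, velocity = velocity)
  motile <- cls != "immotile"
  mean_over_motile <- function(f) {
    if (!any(motile)) return(NA_real_)
    mean(vapply(tracks[motile], f, 0))
  }
  tibble::tibble(
    TM = mean(motile) * 100,
    PM = mean(cls == "progressive") * 100,
    VCL = mean_over_motile(vcl),
    VSL = mean_over_motile(vsl),
    VAP = mean_over_motile(function(t) vap(t, window)),
    n_tracks = length(tracks))
}

#' Simulate a mixed population of sperm tracks
#'
#' Persistent-random-walk simulator with three motility classes. Each
#' motile track has a constant speed drawn per track and a heading that
#' diffuses by a per-frame Gaussian turn; immotile tracks are Brownian
#' positional jitter. The generative class of each track is attached as
#' attribute `classes` (ground truth for classifier checks).
#'
#' Class defaults are well separated with respect to the standard CASA
#' thresholds: immotile ~2 um/s jitter, non-progressive motile ~25 um/s
#' with strong turning, progressive ~45 um/s with mild turning.
#'
#' @param n Number of tracks.
#' @param mixture Named class probabilities (`immotile`, `motile`,
#'   `progressive`); must sum to 1.
#' @param fps Frames per second.
#' @param duration Track duration in seconds.
#' @param class_params Named list of per-class parameters; motile classes
#'   use `speed_mean`, `speed_sd` (um/s) and `turn_sd` (radians/frame),
#'   the immotile class uses `jitter_sd` (um per frame step).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List of [sperm_track]s with attribute `classes`.
#' @export
simulate_tracks <- function(n = 1000,
                            mixture = c(immotile = 0.15, motile = 0.25,
                                        progressive = 0.60),
                            fps = 25, duration = 1,
                            class_params = list(
                              immotile = list(jitter_sd = 0.06),
                              motile = list(speed_mean = 25, speed_sd = 5,
                                            turn_sd = 0.6),
                              progressive = list(speed_mean = 45,
                                                 speed_sd = 6,
                                                 turn_sd = 0.12)),
                            seed = NULL) {
  if (!setequal(names(mixture), c("immotile", "motile", "progressive")))
    stop("`mixture` must name immotile, motile and progressive",
         call. = FALSE)
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    stop("`mixture` probabilities must be non-negative and sum to 1",
         call. = FALSE)
  run <- function() {
    n_frames <- max(2L, round(fps * duration) + 1L)
    classes <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    tracks <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      if (cl == "immotile") {
        sdj <- class_params$immotile$jitter_sd
        x <- cumsum(c(0, rnorm(n_frames - 1, 0, sdj)))
        y <- cumsum(c(0, rnorm(n_frames - 1, 0, sdj)))
      } else {
        p <- class_params[[cl]]
        speed <- max(0.1, rnorm(1, p$speed_mean, p$speed_sd))
        step <- speed / fps
        theta <- runif(1, 0, 2 * pi) +
          cumsum(c(0, rnorm(n_frames - 2, 0, p$turn_sd)))
        x <- cumsum(c(0, step * cos(theta)))
        y <- cumsum(c(0, step * sin(theta)))
      }
      tracks[[i]] <- sperm_track(x, y, fps = fps, track_id = i)
    }
    attr(tracks, "classes") <- classes
    tracks
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
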