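#' Holotomographic freezability index (FI_HT)
#'
#' The ratio of the mean regional volume measured after freezing to the
#' mean volume of the same region in the donor's fresh reference sample,
#' expressed as a percentage: `FI_HT = V_frozen / V_fresh * 100`. 100%
#' means no structural change; values below 100% indicate post-freeze
#' volume loss; values above 100% (legal) indicate swelling.
#'
#' @param v_frozen Mean region volume under the freezing extender, um^3.
#' @param v_fresh Mean region volume of the fresh reference, um^3 (> 0).
#' @return FI_HT in percent (vectorised).
#' @export
fi_ht <- function(v_frozen, v_fresh) {
  if (any(!is.finite(v_fresh)) || any(v_fresh <= 0))
    stop("`v_fresh` must be positive", call. = FALSE)
  if (any(v_frozen < 0)) stop("`v_frozen` must be >= 0", call. = FALSE)
  v_frozen / v_fresh * 100
}

#' Motility freezability index
#'
#' Post-thaw motility related to the pre-freeze value of the same sample.
#' The default mirrors the volume-based index as a ratio
#' (`post / pre * 100`); a difference form (`post - pre`, percentage
#' points) is available since conventions vary across laboratories.
#' Computed separately for TM and PM by the caller.
#'
#' @param post,pre Motility percentages in `[0, 100]`; `pre > 0` for the
#'   ratio form.
#' @param method `"ratio"` (default) or `"difference"`.
#' @return Index in percent (ratio) or percentage points (difference).
#' @export
motility_freezability <- function(post, pre, method = c("ratio",
                                                        "difference")) {
  method <- match.arg(method)
  if (any(post < 0 | post > 100) || any(pre < 0 | pre > 100))
    stop("motility values must lie in [0, 100]", call. = FALSE)
  if (method == "ratio") {
    if (any(pre == 0))
      stop("pre-freeze motility must be > 0 for the ratio index",
           call. = FALSE)
    post / pre * 100
  } else {
    post - pre
  }
}

#' Aggregate per-cell volumes into freezability records
#'
#' For every donor x freezing-extender x region, divides the sample mean
#' volume over cells by the donor's fresh-reference sample mean
#' (mean-of-volumes ratio). Cells are deliberately not paired across
#' arms: different spermatozoa are imaged fresh and frozen, so a per-cell
#' ratio is not defined.
#'
#' @param morph Tibble/data frame with columns `donor`, `extender`,
#'   `region`, `volume` (one row per cell x region, e.g. from
#'   [study_morphometry()]).
#' @param fresh_label Extender label of the fresh reference.
#' @return A [tibble::tibble] with columns `donor`, `extender`, `region`,
#'   `v_fresh`, `v_frozen`, `fi_ht`, `n_cells_fresh`, `n_cells_frozen`.
#' @export
aggregate_freezability <- function(morph, fresh_label = "INRA96") {
  need <- c("donor", "extender", "region", "volume")
  miss <- setdiff(need, names(morph))
  if (length(miss))
    stop("morphometry table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  morph <- tibble::as_tibble(morph)
  fresh <- dplyr::filter(morph, .data$extender == fresh_label)
  donors <- unique(morph$donor)
  missing_fresh <- setdiff(donors, unique(fresh$donor))
  if (length(missing_fresh))
    stop("donor(s) lacking a fresh reference sample: ",
         paste(missing_fresh, collapse = ", "), call. = FALSE)
  fresh_means <- fresh |>
    dplyr::group_by(.data$donor, .data$region) |>
    dplyr::summarise(v_fresh = mean(.data$volume),
                     n_cells_fresh = dplyr::n(), .groups = "drop")
  frozen_means <- morph |>
    dplyr::filter(.data$extender != fresh_label) |>
    dplyr::group_by(.data$donor, .data$extender, .data$region) |>
    dplyr::summarise(v_frozen = mean(.data$volume),
                     n_cells_frozen = dplyr::n(), .groups = "drop")
  dplyr::inner_join(frozen_means, fresh_means,
                    by = c("donor", "region")) |>
    dplyr::mutate(fi_ht = fi_ht(.data$v_frozen, .data$v_fresh)) |>
    dplyr::select("donor", "extender", "region", "v_fresh", "v_frozen",
                  "fi_ht", "n_cells_fresh", "n_cells_frozen") |>
    dplyr::arrange(.data$donor, .data$extender, .data$region)
}

#' Classify donors as good / intermediate / poor coolers
#'
#' A donor is a "good cooler" when FI_HT stays at or above
#' `threshold_good` in all three regions, and a "poor cooler" when any
#' region falls below `threshold_poor` (anchored at 80%, below which
#' shrinkage is substantial); anything else is intermediate. With
#' `pool = "pooled"` (default) a donor's per-region FI_HT is first
#' averaged across freezing extenders; with `"by_extender"` a call is made
#' per donor x extender.
#'
#' @param records Output of [aggregate_freezability()].
#' @param threshold_good,threshold_poor Percent cut-offs in `(0, 100]`.
#' @param pool `"pooled"` or `"by_extender"`.
#' @return A [tibble::tibble] with the per-region FI_HT used and the call.
#' @export
classify_cooler <- function(records, threshold_good = 90,
                            threshold_poor = 80,
                            pool = c("pooled", "by_extender")) {
  pool <- match.arg(pool)
  if (threshold_good <= 0 || threshold_good > 100 ||
      threshold_poor <= 0 || threshold_poor > 100 ||
      threshold_poor > threshold_good)
    stop("thresholds must lie in (0, 100] with poor <= good", call. = FALSE)
  grp <- if (pool == "pooled") c("donor", "region")
         else c("donor", "extender", "region")
  fi <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(fi_ht = mean(.data$fi_ht), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "region", values_from = "fi_ht",
                       names_prefix = "fi_")
  call_one <- function(fis) {
    if (any(fis < threshold_poor)) "poor"
    else if (all(fis >= threshold_good)) "good"
    else "intermediate"
  }
  fi_cols <- grep("^fi_", names(fi), value = TRUE)
  fi$call <- vapply(seq_len(nrow(fi)),
                    function(i) call_one(unlist(fi[i, fi_cols])), "")
  fi
}
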