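#' Arcsine square-root transform of percentages
#'
#' `asin(sqrt(p / 100))`, in radians — the classical variance-stabilising
#' transform applied to motility and freezability percentages before
#' ANOVA. Strictly increasing on `[0, 100]`, mapping 0 to 0 and 100 to
#' pi/2.
#'
#' @param p Percentages in `[0, 100]`.
#' @return Transformed values in radians.
#' @export
arcsine_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 100))
    stop("percentages must lie in [0, 100]", call. = FALSE)
  asin(sqrt(p / 100))
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk on the within-group-centred values (the model residuals
#' of a one-way layout) and Levene's test (median-centred,
#' Brown-Forsythe variant by default) across groups. Mirrors the usual
#' pre-ANOVA screen; downstream ANOVA is not blocked when a check fails,
#' a warning is attached instead.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 3 observations per group).
#' @param center Centring for Levene's test: `"median"` or `"mean"`.
#' @return A [tibble::tibble] with one row per test (`test`, `statistic`,
#'   `p_value`, `n_groups`, `min_group_n`).
#' @export
check_assumptions <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- factor(groups)
  n_by <- table(groups)
  if (any(n_by < 3))
    stop("need >= 3 observations per group for the assumption checks",
         call. = FALSE)
  if (any(tapply(values, groups, stats::var) == 0))
    stop("a group has zero variance; assumption checks are undefined",
         call. = FALSE)
  centred <- values - stats::ave(values, groups)
  sw <- stats::shapiro.test(centred)
  lv <- car::leveneTest(values ~ groups, center = if (center == "median")
    stats::median else mean)
  tibble::tibble(
    test = c("shapiro_wilk", "levene"),
    statistic = c(unname(sw$statistic), lv[1, "F value"]),
    p_value = c(sw$p.value, lv[1, "Pr(>F)"]),
    n_groups = nlevels(groups),
    min_group_n = min(n_by))
}

#' ANOVA with optional arcsine transform and Bonferroni pairwise table
#'
#' Fixed-effects ANOVA over one or two factors (donor and/or extender in
#' the cryotolerance workflow). With two factors the default model is
#' additive (no interaction); set `interaction = TRUE` for the full
#' factorial. Percentages can be arcsine-transformed first. Pairwise
#' comparisons for one factor use pooled-SD t tests with Bonferroni
#' correction: raw p times the number of comparisons, capped at 1.
#'
#' @param data Data frame holding response and factors.
#' @param response Response column name.
#' @param factors Character vector of one or two factor column names.
#' @param transform `"none"` or `"arcsine"` (response is a percentage).
#' @param interaction Include the two-factor interaction term.
#' @param pairwise Optional factor name for the Bonferroni pairwise table.
#' @param alpha Significance threshold recorded in the result.
#' @return A list with `anova` (tibble: term, df, statistic, p_value),
#'   `pairwise` (tibble or `NULL`: group1, group2, p_raw, p_bonferroni,
#'   significant), `transform` and `alpha`.
#' @export
ht_anova <- function(data, response, factors, transform = c("none",
                                                            "arcsine"),
                     interaction = FALSE, pairwise = NULL, alpha = 0.05) {
  transform <- match.arg(transform)
  if (!response %in% names(data))
    stop("response column not found: ", response, call. = FALSE)
  if (!all(factors %in% names(data)))
    stop("factor column(s) not found", call. = FALSE)
  if (length(factors) < 1 || length(factors) > 2)
    stop("`factors` must name one or two columns", call. = FALSE)
  y <- data[[response]]
  if (transform == "arcsine") y <- arcsine_transform(y)
  df <- data.frame(.y = y)
  for (f in factors) {
    fac <- factor(data[[f]])
    if (nlevels(fac) < 2)
      stop(sprintf("factor '%s' needs >= 2 levels", f), call. = FALSE)
    if (any(table(fac) < 2))
      stop(sprintf("factor '%s' needs >= 2 observations per level", f),
           call. = FALSE)
    df[[f]] <- fac
  }
  op <- if (interaction && length(factors) == 2) " * " else " + "
  form <- stats::as.formula(paste(".y ~", paste(factors, collapse = op)))
  fit <- stats::aov(form, data = df)
  at <- stats::anova(fit)
  terms <- rownames(at)
  keep <- terms != "Residuals"
  anova_tab <- tibble::tibble(
    term = trimws(terms[keep]),
    df = at$Df[keep],
    statistic = at$`F value`[keep],
    p_value = at$`Pr(>F)`[keep])
  pw <- NULL
  if (!is.null(pairwise)) {
    if (!pairwise %in% factors)
      stop("`pairwise` must be one of `factors`", call. = FALSE)
    raw <- stats::pairwise.t.test(df$.y, df[[pairwise]],
                                  p.adjust.method = "none",
                                  pool.sd = TRUE)$p.value
    pairs <- which(!is.na(raw), arr.ind = TRUE)
    k <- nrow(pairs)
    pw <- tibble::tibble(
      group1 = rownames(raw)[pairs[, 1]],
      group2 = colnames(raw)[pairs[, 2]],
      p_raw = raw[pairs])
    pw$p_bonferroni <- pmin(pw$p_raw * k, 1)
    pw$significant <- pw$p_bonferroni < alpha
  }
  list(anova = anova_tab, pairwise = pw, transform = transform,
       alpha = alpha)
}

# Five-number box-plot summary of one numeric vector (Tukey whiskers).
box_summary <- function(x) {
  bs <- grDevices::boxplot.stats(x)$stats
  tibble::tibble(n = length(x), whisker_low = bs[1], q1 = bs[2],
                 median = bs[3], q3 = bs[4], whisker_high = bs[5])
}

#' Per-donor and per-extender summary report
#'
#' Builds the box-plot-style summary tables of a cryotolerance study:
#' for each region (and each kinematic metric, when given) the
#' five-number summary (Tukey whiskers, quartiles, median) grouped by
#' donor and, separately, by extender. Optionally writes CSVs and
#' box-plot figures. Output is deterministic given the inputs.
#'
#' @param fi_records Output of [aggregate_freezability()].
#' @param kin_summaries Optional tibble with columns `donor`, `extender`
#'   and kinematic metrics (`TM`, `PM`, `VCL`, `VSL`, `VAP`).
#' @param out_dir Optional directory; CSV tables (and PDF figures when
#'   `plots = TRUE`) are written there.
#' @param plots Write ggplot2 box-plot figures alongside the CSVs.
#' @return A named list of tibbles (`fi_by_donor`, `fi_by_extender`, and
#'   when kinematics are given `kin_by_donor`, `kin_by_extender`).
#' @export
freezability_report <- function(fi_records, kin_summaries = NULL,
                                out_dir = NULL, plots = FALSE) {
  if (nrow(fi_records) == 0) stop("no freezability records", call. = FALSE)
  summarise_by <- function(tab, value_col, by) {
    tab |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::reframe(box_summary(.data[[value_col]])) |>
      dplyr::arrange(dplyr::across(dplyr::all_of(by)))
  }
  out <- list(
    fi_by_donor = summarise_by(fi_records, "fi_ht", c("region", "donor")),
    fi_by_extender = summarise_by(fi_records, "fi_ht",
                                  c("region", "extender")))
  if (!is.null(kin_summaries)) {
    long <- tidyr::pivot_longer(kin_summaries,
                                dplyr::any_of(c("TM", "PM", "VCL", "VSL",
                                                "VAP")),
                                names_to = "metric", values_to = "value")
    out$kin_by_donor <- summarise_by(long, "value", c("metric", "donor"))
    out$kin_by_extender <- summarise_by(long, "value",
                                        c("metric", "extender"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    if (plots) {
      p1 <- ggplot2::ggplot(fi_records,
                            ggplot2::aes(factor(.data$donor),
                                         .data$fi_ht)) +
        ggplot2::geom_boxplot() +
        ggplot2::facet_wrap(~region, scales = "free_y") +
        ggplot2::geom_hline(yintercept = 100, linetype = 2) +
        ggplot2::labs(x = "donor", y = "FI_HT (%)")
      ggplot2::ggsave(file.path(out_dir, "fi_by_donor.pdf"), p1,
                      width = 9, height = 4)
      p2 <- ggplot2::ggplot(fi_records,
                            ggplot2::aes(.data$extender, .data$fi_ht)) +
        ggplot2::geom_boxplot() +
        ggplot2::facet_wrap(~region, scales = "free_y") +
        ggplot2::geom_hline(yintercept = 100, linetype = 2) +
        ggplot2::labs(x = "extender", y = "FI_HT (%)") +
        ggplot2::theme(axis.text.x =
                         ggplot2::element_text(angle = 30, hjust = 1))
      ggplot2::ggsave(file.path(out_dir, "fi_by_extender.pdf"), p2,
                      width = 9, height = 4)
    }
  }
  out
}
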