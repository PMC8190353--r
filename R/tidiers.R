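## broom-style tidiers for the report objects.

#' Tidy a validation report
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return The findings tibble, one row per finding, with `series_uid` and
#'   `verdict` columns prepended.
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(series_uid = rep(x$series_uid, nrow(x$findings)),
                   verdict = rep(x$verdict, nrow(x$findings))),
    x$findings
  )
}

#' @rdname tidy.validation_report
#' @return `glance()` returns a one-row summary: verdict, instance count and
#'   per-severity finding counts.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    series_uid = x$series_uid,
    profile = x$profile,
    n_instances = x$n_instances,
    n_findings = nrow(x$findings),
    n_fail = sum(x$findings$severity == "fail"),
    n_warn = sum(x$findings$severity == "warn"),
    n_info = sum(x$findings$severity == "info"),
    verdict = x$verdict
  )
}

#' Tidy a cohort flow report
#'
#' @param x A `cohort_flow`.
#' @param ... Unused.
#' @return The stage tibble: `stage`, `n` surviving, `discarded`.
#' @method tidy cohort_flow
#' @export
tidy.cohort_flow <- function(x, ...) x$stages

#' @rdname tidy.cohort_flow
#' @method glance cohort_flow
#' @export
glance.cohort_flow <- function(x, ...) {
  tibble::tibble(
    n_intake = x$n_intake,
    n_after_quality = x$n_after_quality,
    n_after_artifact = x$n_after_artifact,
    n_after_validation = x$n_after_validation,
    profile = x$profile
  )
}

#' Tidy a strata allocation
#'
#' @param x A `strata_allocation`.
#' @param ... Unused.
#' @return The allocation tibble (`stratum`, `size`, `quota`, `allocation`).
#' @method tidy strata_allocation
#' @export
tidy.strata_allocation <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("stratum", "size", "quota", "allocation")])
}

#' @rdname tidy.strata_allocation
#' @method glance strata_allocation
#' @export
glance.strata_allocation <- function(x, ...) {
  tibble::tibble(N = attr(x, "N"), n = attr(x, "n"),
                 n_strata = nrow(x))
}

#' Plot a cohort flow as a stage funnel
#'
#' @param object A `cohort_flow`.
#' @param ... Unused.
#' @return A ggplot: surviving series per curation stage.
#' @method autoplot cohort_flow
#' @export
autoplot.cohort_flow <- function(object, ...) {
  df <- object$stages
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3.4) +
    ggplot2::labs(x = NULL, y = "series surviving",
                  title = "Cohort curation flow") +
    ggplot2::theme_minimal()
}

#' Plot one slice of a CT volume
#'
#' @param object A `ct_volume`.
#' @param slice Slice index along z (default: middle slice).
#' @param width,level,gamma Display transform (see [apply_window()]).
#' @param ... Unused.
#' @return A ggplot raster of the windowed slice.
#' @method autoplot ct_volume
#' @export
autoplot.ct_volume <- function(object, slice = NULL,
                               width = 400, level = 40, gamma = 1, ...) {
  nz <- dim(object$data)[3]
  if (is.null(slice)) slice <- ceiling(nz / 2)
  stopifnot(slice >= 1, slice <= nz)
  img <- apply_window(object$data[, , slice], width = width, level = level,
                      gamma = gamma)
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$gray <- as.vector(t(img))  # row-major walk matches expand_grid order
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("slice %d (W=%g, L=%g)", slice, width, level),
                  x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_void()
}

#' Plot classification counts of an index column
#'
#' @param counts A tibble from [classify_counts()].
#' @param column Label for the x axis.
#' @return A ggplot bar chart of counts per bin.
#' @export
plot_classify_counts <- function(counts, column = "bin") {
  counts$bin <- factor(counts$bin, levels = counts$bin)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3.4) +
    ggplot2::labs(x = column, y = "datasets") +
    ggplot2::theme_minimal()
}
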