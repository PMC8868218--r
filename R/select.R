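# Study-level feature selection: which texture features track which blood
# biomarkers across repeated exercise.

#' Select texture features with slopes parallel to blood biomarkers
#'
#' For every (region, biomarker, channel variant, feature) combination,
#' builds the paired series — biomarker value and feature value against the
#' repetition index at the post-exercise sampling time, horses as
#' replicates — and runs [fit_parallelism()]. Within one color model and
#' one biomarker this evaluates 528 pairs (88 features x 3 components x 2
#' normalization states); across the four models, 2112 per region.
#'
#' @param features Long feature table (see [extract_features()]).
#' @param biomarkers Biomarker table with columns `horse`, `re`, `bs` and
#'   the panel parameters.
#' @param targets Biomarkers to test against (default WBC, CPK, AST).
#' @param alpha,alpha_nz Significance levels for the equality and non-zero
#'   slope tests.
#' @param scale `"align"` (default) or `"raw"`; see [fit_parallelism()].
#' @param bs Sampling time whose series are compared (default 1,
#'   post-exercise).
#' @param p_adjust Optional multiple-testing correction (`"none"` by
#'   default, matching per-pair testing at `alpha`; `"BH"` applies
#'   Benjamini-Hochberg to the slope-equality p-values).
#' @return A tibble with one row per evaluated pair: `roi`, `biomarker`,
#'   `model`, `channel`, `normalization`, `feature`, `slope_biomarker`,
#'   `slope_feature`, `p_slope_equal`, `pooled_slope`,
#'   `p_intercept_equal`, `pooled_intercept`, `p_slope_nonzero`,
#'   `related`. Pairs whose feature series is degenerate (constant or with
#'   missing values) carry `related = NA`.
#' @export
select_related <- function(features, biomarkers,
                           targets = c("WBC", "CPK", "AST"),
                           alpha = 0.05, alpha_nz = 0.05,
                           scale = c("align", "raw"), bs = 1,
                           p_adjust = c("none", "BH")) {
  scale <- match.arg(scale)
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(targets %in% names(biomarkers)))

  feats <- dplyr::filter(features, .data$bs == !!bs, .data$model != "IRT")
  bio <- dplyr::filter(biomarkers, .data$bs == !!bs)

  # one series per (horse, re): feature value and each target biomarker
  merged <- dplyr::inner_join(
    feats, dplyr::select(bio, "horse", "re", dplyr::all_of(targets)),
    by = c("horse", "re")
  )

  nested <- tidyr::nest(
    merged,
    data = c("horse", "re", "value", dplyr::all_of(targets)),
    .by = c("roi", "model", "channel", "normalization", "feature")
  )

  rows <- purrr::map(seq_len(nrow(nested)), function(i) {
    d <- nested$data[[i]]
    purrr::map(targets, function(tg) {
      out <- tibble::tibble(
        roi = nested$roi[i], biomarker = tg, model = nested$model[i],
        channel = nested$channel[i], normalization = nested$normalization[i],
        feature = nested$feature[i],
        slope_biomarker = NA_real_, slope_feature = NA_real_,
        p_slope_equal = NA_real_, pooled_slope = NA_real_,
        p_intercept_equal = NA_real_, pooled_intercept = NA_real_,
        p_slope_nonzero = NA_real_, related = NA
      )
      if (anyNA(d$value) || sd(d$value) == 0) return(out)
      pair <- tibble::tibble(
        x = rep(d$re, 2),
        y = c(d[[tg]], d$value),
        group = rep(c(tg, "feature"), each = nrow(d))
      )
      fit <- tryCatch(
        fit_parallelism(
          pair, alpha = alpha, alpha_nz = alpha_nz, scale = scale,
          feature_group = "feature"
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) return(out)   # degenerate pair: related stays NA
      out$slope_biomarker <- unname(fit$slopes[1])
      out$slope_feature <- unname(fit$slopes[2])
      out$p_slope_equal <- fit$p_slope_equal
      out$pooled_slope <- fit$pooled_slope
      out$p_intercept_equal <- fit$p_intercept_equal
      out$pooled_intercept <- fit$pooled_intercept
      out$p_slope_nonzero <- fit$p_slope_nonzero
      out$related <- fit$related
      out
    })
  })
  sel <- dplyr::bind_rows(purrr::flatten(rows))
  if (p_adjust == "BH") {
    sel <- dplyr::mutate(
      sel,
      p_slope_equal = stats::p.adjust(.data$p_slope_equal, "BH"),
      related = .data$p_slope_equal > alpha & .data$p_slope_nonzero < alpha_nz
    )
  }
  sel
}

#' Summarize a selection as a family x component matrix
#'
#' Condenses a [select_related()] result into the summary-matrix view: for
#' each region, feature family and color component, which biomarkers have
#' parallel slopes. Used for the text report and [plot_selection_matrix()].
#'
#' @param selection A [select_related()] result.
#' @return A tibble with columns `roi`, `family`, `model`, `channel`,
#'   `biomarkers` (comma-separated related biomarkers, `""` if none).
#' @export
selection_matrix <- function(selection) {
  sel <- dplyr::mutate(
    selection,
    family = sub("\\..*$", "", .data$feature)
  )
  dplyr::summarise(
    dplyr::group_by(sel, .data$roi, .data$family, .data$model, .data$channel),
    biomarkers = paste(
      sort(unique(.data$biomarker[.data$related %in% TRUE])),
      collapse = ","
    ),
    .groups = "drop"
  )
}

#' @rdname selection_matrix
#' @param file Optional path; when given, a plain-text rendering is
#'   written.
#' @export
write_selection_matrix <- function(selection, file) {
  m <- selection_matrix(selection)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(m, column = paste(m$model, m$channel, sep = ".")),
    id_cols = c("roi", "family"), names_from = "column",
    values_from = "biomarkers", values_fill = ""
  )
  readr::write_delim(wide, file, delim = "\t")
  invisible(wide)
}

#' Plot the selection summary matrix
#'
#' Tile plot of [selection_matrix()]: feature family against color
#' component, faceted by region, tiles labeled with the related biomarkers.
#'
#' @param selection A [select_related()] result.
#' @return A ggplot object.
#' @export
plot_selection_matrix <- function(selection) {
  m <- dplyr::mutate(
    selection_matrix(selection),
    component = paste(.data$model, .data$channel, sep = "."),
    any = .data$biomarkers != ""
  )
  ggplot2::ggplot(
    m, ggplot2::aes(x = .data$component, y = .data$family, fill = .data$any)
  ) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$biomarkers), size = 2.5) +
    ggplot2::facet_wrap(~roi, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#fdae61", `FALSE` = "white"), guide = "none"
    ) +
    ggplot2::labs(x = "color component", y = "feature family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot a thermogram or temperature field
#'
#' @param x A temperature matrix or an `h x w x 3` RGB array.
#' @return A ggplot object.
#' @export
plot_thermogram <- function(x) {
  if (is.matrix(x)) {
    d <- tidyr::expand_grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
    d$value <- as.vector(t(x))
    ggplot2::ggplot(
      d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)
    ) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(option = "inferno", name = "deg C") +
      ggplot2::coord_equal() +
      ggplot2::theme_void()
  } else {
    d <- tidyr::expand_grid(row = seq_len(dim(x)[1]), col = seq_len(dim(x)[2]))
    d$hex <- grDevices::rgb(
      as.vector(t(x[, , 1])), as.vector(t(x[, , 2])), as.vector(t(x[, , 3])),
      maxColorValue = 255
    )
    ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$hex)) +
      ggplot2::scale_fill_identity() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_equal() +
      ggplot2::theme_void()
  }
}
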