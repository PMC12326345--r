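#' Root-mean-square error between measured and predicted strengths
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_{i=1}^n
#'   (\sigma_{measured,i} - \sigma_{predicted,i})^2}.}
#'
#' @param measured,predicted Equal-length, non-empty numeric vectors, MPa.
#' @return RMSE in MPa.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 5))  # sqrt(4/3)
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) == 0 || length(measured) != length(predicted)) {
    stop_compactmix("evaluation",
                    "measured and predicted must be non-empty and equal length.")
  }
  if (any(!is.finite(measured)) || any(!is.finite(predicted))) {
    stop_compactmix("evaluation", "inputs must be finite.")
  }
  sqrt(mean((measured - predicted)^2))
}

#' Compare mixing models against measured mixture data
#'
#' For every mixture and every candidate model, predicts tensile strength at
#' each measured tablet's actual porosity (no binning) via
#' [predict_mixture_profile()], then reports RMSE per mixture and a global
#' RMSE per model. The global RMSE pools squared residuals across all
#' mixtures (it is not a mean of per-mixture RMSEs), so
#' \eqn{\mathrm{RMSE}_{global}^2} equals the point-count-weighted mean of the
#' per-mixture \eqn{\mathrm{RMSE}^2}. Models are ranked by global RMSE, ties
#' broken in favour of the simpler model (lower interaction order first).
#'
#' @param data Measured-mixture table: columns `mixture_id`, `porosity`,
#'   `tensile_strength` (measured, MPa).
#' @param compositions Per-mixture composition table: columns `mixture_id`,
#'   `material`, `volume_fraction`.
#' @param profiles Named list of `rd_fit` profiles or a profile table
#'   covering every material appearing in `compositions`.
#' @param models Character vector of model ids (see
#'   [predict_mixture_profile()]); `"interaction-<n>"` fixes the order.
#' @return A `model_comparison` object: list with `pairs` (every
#'   mixture x model x point with measured and predicted values), `by_mixture`
#'   (per-mixture RMSE), and `global` (per-model pooled RMSE, n and rank).
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
evaluate_models <- function(data, compositions, profiles,
                            models = c("interaction-2", "interaction-3",
                                       "interaction-4", "interaction-5",
                                       "interaction-6", "linear", "power")) {
  data <- tibble::as_tibble(data)
  needed <- c("mixture_id", "porosity", "tensile_strength")
  if (!all(needed %in% names(data))) {
    stop_compactmix("evaluation", sprintf(
      "measured data must have columns: %s.", paste(needed, collapse = ", ")))
  }
  compositions <- tibble::as_tibble(compositions)
  specs <- lapply(models, parse_model_id)
  ids <- vapply(specs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_compactmix("configuration", "duplicate model ids in `models`.")
  }
  profiles <- as_profile_list(profiles, unique(compositions$material))

  comp_list <- compositions |>
    dplyr::group_by(.data$mixture_id) |>
    dplyr::group_map(~ composition(.x$material, .x$volume_fraction)) |>
    stats::setNames(sort(unique(compositions$mixture_id)))
  missing_comp <- setdiff(unique(data$mixture_id), names(comp_list))
  if (length(missing_comp) > 0) {
    stop_compactmix("configuration", sprintf(
      "no composition given for mixture(s): %s",
      paste(missing_comp, collapse = ", ")))
  }

  pairs <- purrr::map(unique(data$mixture_id), function(mx) {
    meas <- dplyr::filter(data, .data$mixture_id == mx)
    purrr::map(ids, function(id) {
      pred <- predict_mixture_profile(profiles, comp_list[[mx]],
                                      meas$porosity, model = id)
      tibble::tibble(mixture_id = mx, model = id,
                     porosity = meas$porosity,
                     measured = meas$tensile_strength,
                     predicted = pred$tensile_strength)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  by_mixture <- pairs |>
    dplyr::group_by(.data$mixture_id, .data$model) |>
    dplyr::summarise(rmse = rmse(.data$measured, .data$predicted),
                     n_points = dplyr::n(), .groups = "drop")

  complexity <- stats::setNames(
    vapply(specs, function(s) model_complexity(s), numeric(1)), ids)
  global <- pairs |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(rmse = rmse(.data$measured, .data$predicted),
                     n_points = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(complexity = complexity[.data$model]) |>
    dplyr::arrange(.data$rmse, .data$complexity, .data$model) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select(-"complexity")

  structure(list(pairs = pairs, by_mixture = by_mixture, global = global),
            class = "model_comparison")
}

# Tie-break key: interaction order where defined; linear is equivalent to a
# pairwise model, power is the infinite-order limit; rd-* rules sit outside
# the order hierarchy and rank after exact-order models at equal RMSE.
model_complexity <- function(spec) {
  switch(spec$family,
         interaction = spec$order,
         linear = 2,
         power = Inf,
         rd = Inf)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison over", length(unique(x$pairs$mixture_id)),
      "mixture(s),", nrow(x$global), "model(s)\n\n")
  print(as.data.frame(x$global), row.names = FALSE)
  invisible(x)
}

#' Per-mixture RMSE table of a model comparison
#'
#' @param x A `model_comparison` from [evaluate_models()].
#' @param ... Unused.
#' @return A tibble: `mixture_id`, `model`, `rmse` (MPa), `n_points`.
#' @export
tidy.model_comparison <- function(x, ...) x$by_mixture

#' Global model ranking of a model comparison
#'
#' @param x A `model_comparison` from [evaluate_models()].
#' @param ... Unused.
#' @return A tibble: `model`, `rmse` (pooled global RMSE, MPa), `n_points`,
#'   `rank`.
#' @export
glance.model_comparison <- function(x, ...) x$global

#' @export
autoplot.model_comparison <- function(object, ...) {
  dat <- dplyr::mutate(object$global,
                       model = stats::reorder(.data$model, .data$rmse))
  ggplot2::ggplot(dat, ggplot2::aes(.data$model, .data$rmse)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "overall RMSE (MPa)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
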