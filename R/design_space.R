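#' Formulation design space for a target strength window
#'
#' Screens a composition x porosity grid for the region predicted to meet a
#' tensile-strength specification, using only the pure components'
#' compactibility profiles. For a binary system the composition grid runs
#' over the first component's volume fraction; for a ternary system over a
#' simplex grid of the first two components.
#'
#' At fixed porosity in a binary system the interaction model is monotone in
#' the strong component's volume fraction, so the acceptable region is a
#' contiguous interval of compositions.
#'
#' @param profiles Named list of `rd_fit` profiles or a profile table.
#' @param materials Character vector of 2 or 3 component materials.
#' @param target Length-2 numeric: acceptable strength window
#'   `c(low, high)` in MPa, `low < high`.
#' @param composition_step Grid step for volume fractions (> 0).
#' @param porosity Porosity grid (non-empty, in `[0, 1)`).
#' @param model,order Mixing model and interaction order (see
#'   [predict_mixture_profile()]).
#' @return A `design_space` tibble: one row per grid cell with the component
#'   volume fractions (`V_<material>`), `porosity`, `tensile_strength`
#'   (predicted, MPa) and `acceptable` (logical mask,
#'   `low <= prediction <= high`). Supports [ggplot2::autoplot()].
#' @examples
#' profs <- list(A = rd_profile("A", 12, 6), B = rd_profile("B", 2, 9))
#' ds <- design_space(profs, c("A", "B"), target = c(1, 2),
#'                    porosity = c(0.15, 0.2))
#' @export
design_space <- function(profiles, materials, target,
                         composition_step = 0.05,
                         porosity = seq(0.10, 0.30, by = 0.05),
                         model = "interaction", order = 4) {
  if (length(materials) < 2 || length(materials) > 3) {
    stop_compactmix("configuration", "design_space supports 2 or 3 components.")
  }
  if (length(target) != 2 || !all(is.finite(target)) || target[1] >= target[2]) {
    stop_compactmix("configuration", "target must be c(low, high) with low < high.")
  }
  if (composition_step <= 0) {
    stop_compactmix("configuration", "composition_step must be > 0.")
  }
  if (length(porosity) == 0) {
    stop_compactmix("configuration", "porosity grid is empty.")
  }
  profiles <- as_profile_list(profiles, materials)
  v1 <- seq(0, 1, by = composition_step)
  if (length(materials) == 2) {
    comps <- tibble::tibble(V1 = v1, V2 = 1 - v1)
  } else {
    comps <- tidyr::expand_grid(V1 = v1, V2 = v1) |>
      dplyr::filter(.data$V1 + .data$V2 <= 1 + 1e-12) |>
      dplyr::mutate(V3 = pmax(0, 1 - .data$V1 - .data$V2))
  }
  names(comps) <- paste0("V_", materials)
  grid <- tidyr::expand_grid(comps, porosity = porosity)
  sig <- purrr::pmap_dbl(grid, function(...) {
    row <- list(...)
    v <- unlist(row[paste0("V_", materials)])
    predict_mixture_profile(profiles, composition(materials, v),
                            row$porosity, model = model,
                            order = order)$tensile_strength
  })
  out <- dplyr::mutate(grid, tensile_strength = sig,
                       acceptable = sig >= target[1] & sig <= target[2])
  attr(out, "target") <- target
  attr(out, "materials") <- materials
  class(out) <- c("design_space", class(out))
  out
}

#' @export
autoplot.design_space <- function(object, ...) {
  mats <- attr(object, "materials")
  v1 <- paste0("V_", mats[1])
  ggplot2::ggplot(object,
                  ggplot2::aes(.data[[v1]], .data$porosity,
                               fill = .data$acceptable)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "grey85")) +
    ggplot2::labs(x = paste("volume fraction of", mats[1]),
                  y = "porosity",
                  fill = sprintf("within %.2g-%.2g MPa",
                                 attr(object, "target")[1],
                                 attr(object, "target")[2]))
}
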