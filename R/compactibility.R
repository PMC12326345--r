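#' Tablet porosity from raw measurements
#'
#' Computes the porosity of a compacted tablet from its weight, envelope
#' dimensions and the true (skeletal) density of the powder,
#' \deqn{\varepsilon = 1 - \frac{4W}{\pi D^2 t \rho}.}
#'
#' Units follow the usual tableting-lab convention: weight in grams, diameter
#' and thickness in millimetres, true density in g/cm^3. The mm-to-cm
#' conversion is handled internally so that mass and volume units cancel.
#'
#' @param data A data frame with one row per tablet.
#' @param weight,diameter,thickness,true_density Columns (tidy-eval) holding
#'   tablet weight (g), diameter (mm), thickness (mm) and powder true density
#'   (g/cm^3). Defaults match the column names written by
#'   [generate_tablet_table()] and read by [read_tablet_table()].
#' @return The input as a tibble with two added columns: `porosity`
#'   (dimensionless fraction) and `porosity_flag` (`TRUE` where the computed
#'   porosity is <= 0, i.e. the implied solid fraction is >= 1, which signals
#'   inconsistent inputs; such rows are returned, not dropped).
#' @examples
#' tab <- tibble::tibble(weight_g = 0.5, diameter_mm = 13, thickness_mm = 3,
#'                       true_density_g_cm3 = 1.5)
#' tablet_porosity(tab)
#' @export
tablet_porosity <- function(data, weight = weight_g, diameter = diameter_mm,
                            thickness = thickness_mm,
                            true_density = true_density_g_cm3) {
  data <- tibble::as_tibble(data)
  w <- dplyr::pull(data, {{ weight }})
  d <- dplyr::pull(data, {{ diameter }})
  t <- dplyr::pull(data, {{ thickness }})
  rho <- dplyr::pull(data, {{ true_density }})
  check_positive_measurements(w, d, t, rho)
  # D, t in mm -> cm so envelope volume is cm^3, matching g / (g cm^-3)
  eps <- 1 - (4 * w) / (pi * (d / 10)^2 * (t / 10) * rho)
  dplyr::mutate(data, porosity = eps, porosity_flag = eps <= 0)
}

#' Diametral tensile strength from a crushing test
#'
#' Converts the failure force of a diametral compression (Brazilian) test
#' into a tensile strength via \deqn{\sigma = \frac{2F}{\pi D t}.}
#' With force in newtons and dimensions in millimetres the result is in MPa
#' (N/mm^2) directly.
#'
#' @param data A data frame with one row per tablet.
#' @param force,diameter,thickness Columns holding failure force (N),
#'   diameter (mm) and thickness (mm).
#' @return The input as a tibble with an added `tensile_strength` column (MPa).
#' @examples
#' tab <- tibble::tibble(force_N = 100, diameter_mm = 13, thickness_mm = 3)
#' diametral_tensile_strength(tab)
#' @export
diametral_tensile_strength <- function(data, force = force_N,
                                       diameter = diameter_mm,
                                       thickness = thickness_mm) {
  data <- tibble::as_tibble(data)
  f <- dplyr::pull(data, {{ force }})
  d <- dplyr::pull(data, {{ diameter }})
  t <- dplyr::pull(data, {{ thickness }})
  if (any(!is.finite(f)) || any(f < 0)) {
    stop_compactmix("invalid_measurement",
                    "`force` must be finite and non-negative.")
  }
  check_positive_measurements(d = d, t = t)
  dplyr::mutate(data, tensile_strength = 2 * f / (pi * d * t))
}

#' Reduce a raw tablet table to compactibility points
#'
#' Convenience wrapper applying [tablet_porosity()] and
#' [diametral_tensile_strength()] to a raw tablet measurement table,
#' returning one `(porosity, tensile_strength)` point per tablet.
#'
#' @param data A tablet table with columns `material`, `weight_g`,
#'   `diameter_mm`, `thickness_mm`, `force_N`, `true_density_g_cm3`.
#' @return A tibble with columns `material`, `porosity`, `tensile_strength`,
#'   `porosity_flag`.
#' @export
compact_points <- function(data) {
  data |>
    tablet_porosity() |>
    diametral_tensile_strength() |>
    dplyr::select(dplyr::any_of("material"), "porosity",
                  "tensile_strength", "porosity_flag")
}

#' Fit a Ryshkewitch-Duckworth compactibility profile
#'
#' Fits \eqn{\sigma = \sigma_0 e^{-k \varepsilon}} to porosity /
#' tensile-strength points by nonlinear least squares in linear strength
#' space (Levenberg-Marquardt), initialised from ordinary least squares on
#' \eqn{\ln\sigma} vs \eqn{\varepsilon}. Fitting in linear space avoids the
#' log-transform's implicit down-weighting of high-strength points; the
#' log-space estimate is retained as `init` so either choice is auditable
#' from the residuals.
#'
#' Points with zero tensile strength (tablets that failed to form or had no
#' measurable strength) cannot enter an exponential fit; they are excluded
#' and counted in `n_excluded`.
#'
#' @param data A data frame of points.
#' @param porosity,tensile_strength Columns holding the porosity fraction and
#'   strength in MPa.
#' @param material_id Label stored on the returned profile.
#' @return An object of class `rd_fit` with elements `material_id`, `sigma0`,
#'   `k`, `eps_range` (fitted porosity range), `n_points`, `n_excluded`,
#'   `rss`, `residuals`, `data`, `init` (log-space OLS start values), and
#'   `converged`. Supports [tidy()], [glance()], [predict()] and
#'   [ggplot2::autoplot()].
#' @examples
#' pts <- tibble::tibble(porosity = seq(0.1, 0.3, by = 0.05),
#'                       tensile_strength = 10 * exp(-8 * porosity))
#' fit <- fit_rd(pts, material_id = "demo")
#' glance(fit)
#' @export
fit_rd <- function(data, porosity = porosity,
                   tensile_strength = tensile_strength,
                   material_id = "material") {
  data <- tibble::as_tibble(data)
  eps <- dplyr::pull(data, {{ porosity }})
  sig <- dplyr::pull(data, {{ tensile_strength }})
  if (any(!is.finite(eps)) || any(!is.finite(sig)) || any(sig < 0)) {
    stop_compactmix("invalid_measurement",
                    "porosity and tensile strength must be finite, strength >= 0.")
  }
  usable <- sig > 0
  n_excluded <- sum(!usable)
  eps_u <- eps[usable]
  sig_u <- sig[usable]
  if (length(eps_u) < 3L) {
    stop_compactmix(
      "insufficient_data",
      sprintf("R-D fit needs >= 3 points with positive strength; got %d (%d excluded as zero-strength).",
              length(eps_u), n_excluded))
  }
  # log-space OLS initialiser: ln sigma = ln sigma0 - k * eps
  ols <- stats::lm(log(sig_u) ~ eps_u)
  start <- list(sigma0 = exp(unname(stats::coef(ols)[1])),
                k = -unname(stats::coef(ols)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(sig_u ~ sigma0 * exp(-k * eps_u),
                      start = start,
                      lower = c(sigma0 = .Machine$double.eps, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    cnd <- rlang::error_cnd(
      class = c("compactmix_fit_failure", "compactmix_error"),
      message = paste0("R-D nonlinear fit failed to converge: ",
                       conditionMessage(fit),
                       " (log-linear fallback estimate attached as $fallback)"),
      fallback = start)
    rlang::cnd_signal(cnd)
  }
  co <- stats::coef(fit)
  structure(
    list(material_id = material_id,
         sigma0 = unname(co["sigma0"]),
         k = unname(co["k"]),
         eps_range = range(eps_u),
         n_points = length(eps_u),
         n_excluded = n_excluded,
         rss = sum(stats::resid(fit)^2),
         residuals = tibble::tibble(porosity = eps_u,
                                    tensile_strength = sig_u,
                                    fitted = stats::fitted(fit),
                                    residual = stats::resid(fit)),
         init = start,
         converged = TRUE),
    class = "rd_fit")
}

#' Construct a compactibility profile from known parameters
#'
#' Builds the same object returned by [fit_rd()] when the
#' Ryshkewitch-Duckworth parameters are supplied directly (e.g. taken from a
#' published table) rather than fitted. No porosity range is recorded, so
#' predictions never warn about extrapolation.
#'
#' @param material_id Material label.
#' @param sigma0 Zero-porosity tensile strength, MPa (> 0).
#' @param k Bonding-capacity constant, dimensionless (> 0).
#' @return An `rd_fit` object with `eps_range = NULL`.
#' @export
rd_profile <- function(material_id, sigma0, k) {
  if (!is.finite(sigma0) || sigma0 <= 0 || !is.finite(k) || k <= 0) {
    stop_compactmix("invalid_profile", "sigma0 and k must be positive and finite.")
  }
  structure(
    list(material_id = material_id, sigma0 = sigma0, k = k,
         eps_range = NULL, n_points = 0L, n_excluded = 0L,
         rss = NA_real_, residuals = NULL, init = NULL, converged = NA),
    class = "rd_fit")
}

#' Predict tensile strength from a compactibility profile
#'
#' Evaluates \eqn{\sigma_0 e^{-k\varepsilon}} at the requested porosities.
#' A warning is raised when a porosity lies outside the porosity window the
#' profile was fitted on (when known): the exponential form extrapolates
#' smoothly but the extrapolation is unvalidated.
#'
#' @param object An `rd_fit` profile.
#' @param porosity Numeric vector of porosities in `[0, 1)`.
#' @param ... Unused.
#' @return Numeric vector of tensile strengths, MPa.
#' @export
predict.rd_fit <- function(object, porosity, ...) {
  if (any(!is.finite(porosity)) || any(porosity < 0) || any(porosity >= 1)) {
    stop_compactmix("domain", "porosity must lie in [0, 1).")
  }
  # tolerance absorbs float round-trip at the window edges
  tol <- 1e-8
  if (!is.null(object$eps_range) &&
      any(porosity < object$eps_range[1] - tol |
            porosity > object$eps_range[2] + tol)) {
    warning(sprintf(
      "extrapolating '%s' outside fitted porosity range [%.3f, %.3f]",
      object$material_id, object$eps_range[1], object$eps_range[2]),
      call. = FALSE)
  }
  object$sigma0 * exp(-object$k * porosity)
}

#' @export
print.rd_fit <- function(x, ...) {
  cat(sprintf("Ryshkewitch-Duckworth profile '%s'\n", x$material_id))
  cat(sprintf("  sigma0 = %.4g MPa, k = %.4g\n", x$sigma0, x$k))
  if (!is.null(x$eps_range)) {
    cat(sprintf("  fitted on %d points, porosity %.3f-%.3f, RSS %.4g (%d zero-strength excluded)\n",
                x$n_points, x$eps_range[1], x$eps_range[2], x$rss, x$n_excluded))
  } else {
    cat("  parameters supplied directly (no fit data)\n")
  }
  invisible(x)
}

#' Tidy a fitted compactibility profile
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`sigma0`, `k`).
#' @export
tidy.rd_fit <- function(x, ...) {
  tibble::tibble(material = x$material_id,
                 term = c("sigma0", "k"),
                 estimate = c(x$sigma0, x$k),
                 unit = c("MPa", "1"))
}

#' One-row summary of a fitted compactibility profile
#'
#' @param x An `rd_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `material`, `sigma0`, `k`, `eps_min`, `eps_max`,
#'   `n_points`, `n_excluded`, `rss`.
#' @export
glance.rd_fit <- function(x, ...) {
  tibble::tibble(material = x$material_id,
                 sigma0 = x$sigma0, k = x$k,
                 eps_min = if (is.null(x$eps_range)) NA_real_ else x$eps_range[1],
                 eps_max = if (is.null(x$eps_range)) NA_real_ else x$eps_range[2],
                 n_points = x$n_points,
                 n_excluded = x$n_excluded,
                 rss = x$rss)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.rd_fit <- function(object, n = 101, ...) {
  rng <- object$eps_range %||% c(0, 0.5)
  grid <- tibble::tibble(porosity = seq(rng[1], rng[2], length.out = n))
  grid$tensile_strength <- object$sigma0 * exp(-object$k * grid$porosity)
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$porosity, .data$tensile_strength)) +
    ggplot2::geom_line(linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "porosity", y = "tensile strength (MPa)",
                  title = sprintf("%s: sigma0 = %.3g MPa, k = %.3g",
                                  object$material_id, object$sigma0, object$k))
  if (!is.null(object$residuals)) {
    p <- p + ggplot2::geom_point(data = object$residuals)
  }
  p
}

#' Fit compactibility profiles for every material in a point table
#'
#' Groups a `(material, porosity, tensile_strength)` table by material, fits
#' each group with [fit_rd()], and returns a per-material parameter table of
#' the shape written by [write_profile_table()].
#'
#' @param data A data frame with columns `material`, `porosity`,
#'   `tensile_strength` (e.g. from [compact_points()]).
#' @return A tibble with one row per material: `material`, `sigma0_MPa`, `k`,
#'   `eps_min`, `eps_max`, `n_points`, `n_excluded`, `rss`.
#' @export
fit_rd_profiles <- function(data) {
  data |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$material) |>
    dplyr::group_map(~ {
      g <- glance(fit_rd(.x, material_id = .y$material))
      dplyr::rename(g, sigma0_MPa = "sigma0")
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$material)
}

#' Rebuild `rd_fit` profiles from a profile parameter table
#'
#' Inverse of [fit_rd_profiles()] / [read_profile_table()]: converts a
#' per-material parameter table into a named list of `rd_fit` objects usable
#' by the mixture-prediction functions.
#'
#' @param data A data frame with columns `material`, `sigma0_MPa`, `k` and
#'   optionally `eps_min`, `eps_max`.
#' @return A named list of `rd_fit` objects keyed by material.
#' @export
profiles_from_table <- function(data) {
  data <- tibble::as_tibble(data)
  out <- purrr::pmap(
    list(data$material, data$sigma0_MPa, data$k,
         data$eps_min %||% rep(NA_real_, nrow(data)),
         data$eps_max %||% rep(NA_real_, nrow(data))),
    function(m, s0, k, lo, hi) {
      p <- rd_profile(m, s0, k)
      if (is.finite(lo) && is.finite(hi)) p$eps_range <- c(lo, hi)
      p
    })
  stats::setNames(out, data$material)
}

check_positive_measurements <- function(...) {
  vals <- list(...)
  nm <- names(vals) %||% rep("", length(vals))
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop_compactmix("invalid_measurement",
                      "tablet measurements must be finite and strictly positive.")
    }
  }
  invisible(TRUE)
}
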