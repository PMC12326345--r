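#' Specification for the synthetic-data generator
#'
#' Bundles the ground-truth material parameters and noise model used by
#' [generate_pure_component_points()], [generate_tablet_table()] and
#' [generate_mixture_dataset()]. The defaults emulate a routine tableting
#' study: 13 mm flat-faced tooling, 500 mg tablets, porosities 0.10-0.30,
#' three replicate tablets per porosity, and a two-component system pairing a
#' strongly bonding material with a much weaker one (the regime in which
#' mixing models actually disagree; with similar component strengths all
#' models converge and cannot be discriminated).
#'
#' Strength noise is multiplicative lognormal (tablet strength scatter scales
#' with magnitude); dimension noise is additive Gaussian on the caliper
#' measurements.
#'
#' @param materials Tibble with columns `material`, `sigma0` (MPa), `k`,
#'   `true_density` (g/cm^3).
#' @param porosities Target porosity grid (fractions in `[0, 1)`).
#' @param replicates Tablets per porosity level.
#' @param noise_sd Lognormal sigma of the multiplicative strength noise.
#' @param dim_noise_sd Additive Gaussian sd on dimensions, mm.
#' @param diameter_mm,weight_g Tooling diameter and target tablet weight.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(materials = default_materials(),
                           porosities = seq(0.10, 0.30, by = 0.05),
                           replicates = 3,
                           noise_sd = 0.05,
                           dim_noise_sd = 0,
                           diameter_mm = 13,
                           weight_g = 0.5) {
  materials <- tibble::as_tibble(materials)
  stopifnot(all(c("material", "sigma0", "k", "true_density") %in% names(materials)))
  if (any(materials$sigma0 <= 0) || any(materials$k <= 0) ||
      any(materials$true_density <= 0)) {
    stop_compactmix("configuration",
                    "sigma0, k and true_density must be positive.")
  }
  if (noise_sd < 0 || dim_noise_sd < 0) {
    stop_compactmix("configuration", "noise sds must be >= 0.")
  }
  if (any(porosities < 0) || any(porosities >= 1)) {
    stop_compactmix("domain", "porosities must lie in [0, 1).")
  }
  structure(list(materials = materials, porosities = porosities,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 dim_noise_sd = dim_noise_sd, diameter_mm = diameter_mm,
                 weight_g = weight_g),
            class = "generator_spec")
}

#' Default two-material system: one strong binder and one weak,
#' poorly-compacting material (strength ratio ~20x at moderate porosity),
#' the configuration under which interaction orders are distinguishable.
#' @return A tibble usable as the `materials` field of [generator_spec()].
#' @export
default_materials <- function() {
  tibble::tibble(
    material = c("strong", "weak"),
    sigma0 = c(12, 2.5),
    k = c(6, 11),
    true_density = c(1.55, 1.30))
}

#' Generate pure-component compactibility points
#'
#' Draws `(porosity, tensile_strength)` points for every material in the
#' spec: at each porosity and replicate, strength is the material's
#' Ryshkewitch-Duckworth value times lognormal noise
#' \eqn{\exp(N(0, sd^2))}. Deterministic under `seed`.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return A tibble: `material`, `porosity`, `tensile_strength` (MPa),
#'   `replicate`.
#' @export
generate_pure_component_points <- function(spec = generator_spec(), seed = 1) {
  out <- with_seed(seed, {
    tidyr::expand_grid(material = spec$materials$material,
                       porosity = spec$porosities,
                       replicate = seq_len(spec$replicates)) |>
      dplyr::left_join(spec$materials, by = "material") |>
      dplyr::mutate(
        tensile_strength = .data$sigma0 * exp(-.data$k * .data$porosity) *
          exp(stats::rnorm(dplyr::n(), 0, spec$noise_sd))) |>
      dplyr::select("material", "porosity", "tensile_strength", "replicate")
  })
  out
}

#' Generate a raw tablet measurement table
#'
#' Produces the delimited-table form consumed by [compact_points()] and the
#' CLI `fit` subcommand: per tablet weight, diameter, thickness, failure
#' force and true density, back-calculated so that the exact porosity and
#' (noisy) strength are recovered by [tablet_porosity()] and
#' [diametral_tensile_strength()]. Thickness is set from the target porosity
#' at fixed weight and diameter; optional Gaussian dimension noise perturbs
#' diameter and thickness after the force has been computed, mimicking
#' caliper error.
#'
#' @inheritParams generate_pure_component_points
#' @return A tibble: `material`, `weight_g`, `diameter_mm`, `thickness_mm`,
#'   `force_N`, `true_density_g_cm3`.
#' @export
generate_tablet_table <- function(spec = generator_spec(), seed = 1) {
  pts <- generate_pure_component_points(spec, seed)
  tab <- pts |>
    dplyr::left_join(spec$materials, by = "material") |>
    dplyr::mutate(
      weight_g = spec$weight_g,
      diameter_mm = spec$diameter_mm,
      # thickness (mm) giving the target porosity: t = 4W / (pi D^2 rho (1-eps))
      thickness_mm = 4 * .data$weight_g /
        (pi * (.data$diameter_mm / 10)^2 * .data$true_density *
           (1 - .data$porosity)) * 10,
      force_N = .data$tensile_strength * pi * .data$diameter_mm *
        .data$thickness_mm / 2)
  if (spec$dim_noise_sd > 0) {
    tab <- with_seed(seed + 1L, dplyr::mutate(
      tab,
      diameter_mm = .data$diameter_mm +
        stats::rnorm(dplyr::n(), 0, spec$dim_noise_sd),
      thickness_mm = .data$thickness_mm +
        stats::rnorm(dplyr::n(), 0, spec$dim_noise_sd)))
  }
  dplyr::select(tab, "material", "weight_g", "diameter_mm", "thickness_mm",
                "force_N", true_density_g_cm3 = "true_density")
}

#' Simulate measured mixture compactibility data under a known model
#'
#' Generates a measured-mixture table of the shape consumed by
#' [evaluate_models()], with ground truth from a chosen mixing model: for
#' each composition, porosity and replicate, the "measured" strength is the
#' model's prediction (components evaluated at that same porosity from their
#' noiseless R-D parameters) times lognormal noise.
#'
#' @inheritParams generate_pure_component_points
#' @param compositions A list of volume-fraction vectors over the spec's
#'   materials (each summing to 1), or a tibble with columns `mixture_id`,
#'   `material`, `volume_fraction`. Default: the 75-25, 50-50 and 25-75
#'   binary ratios.
#' @param truth_model Model id generating the data (see
#'   [predict_mixture_profile()]).
#' @param truth_order Interaction order when `truth_model = "interaction"`.
#' @return A list with `data` (tibble `mixture_id`, `porosity`,
#'   `tensile_strength`, `replicate`), `compositions` (tibble `mixture_id`,
#'   `material`, `volume_fraction`) and `profiles` (the ground-truth
#'   `rd_fit` list), ready to pass to [evaluate_models()].
#' @export
generate_mixture_dataset <- function(spec = generator_spec(),
                                     compositions = NULL,
                                     truth_model = "interaction",
                                     truth_order = 4,
                                     seed = 1) {
  mats <- spec$materials
  profiles <- stats::setNames(
    purrr::pmap(mats, function(material, sigma0, k, true_density)
      rd_profile(material, sigma0, k)),
    mats$material)
  if (is.null(compositions)) {
    if (nrow(mats) != 2) {
      stop_compactmix("configuration",
                      "default compositions require exactly 2 materials.")
    }
    compositions <- lapply(c(0.75, 0.50, 0.25), function(v) c(v, 1 - v))
  }
  if (is.data.frame(compositions)) {
    comp_tbl <- tibble::as_tibble(compositions)
  } else {
    comp_tbl <- purrr::imap(compositions, function(v, i) {
      tibble::tibble(
        mixture_id = sprintf("mix_%02d", as.integer(i)),
        material = mats$material,
        volume_fraction = v)
    }) |> dplyr::bind_rows()
  }
  spec_model <- parse_model_id(truth_model, truth_order)

  grid <- tidyr::expand_grid(
    mixture_id = unique(comp_tbl$mixture_id),
    porosity = spec$porosities,
    replicate = seq_len(spec$replicates))
  truth <- grid |>
    dplyr::distinct(.data$mixture_id, .data$porosity) |>
    dplyr::group_by(.data$mixture_id) |>
    dplyr::group_modify(~ {
      cc <- dplyr::filter(comp_tbl, .data$mixture_id == .y$mixture_id)
      pred <- predict_mixture_profile(
        profiles, composition(cc$material, cc$volume_fraction),
        .x$porosity, model = spec_model$id)
      tibble::tibble(porosity = .x$porosity, truth = pred$tensile_strength)
    }) |>
    dplyr::ungroup()
  data <- with_seed(seed, {
    grid |>
      dplyr::left_join(truth, by = c("mixture_id", "porosity")) |>
      dplyr::mutate(tensile_strength = .data$truth *
                      exp(stats::rnorm(dplyr::n(), 0, spec$noise_sd))) |>
      dplyr::select("mixture_id", "porosity", "tensile_strength", "replicate")
  })
  list(data = data, compositions = comp_tbl, profiles = profiles,
       truth_model = spec_model$id)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
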