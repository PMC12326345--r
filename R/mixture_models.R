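#' Build a mixture composition from volume fractions
#'
#' A composition is a tibble with one row per component and columns
#' `material` and `volume_fraction`. Fractions must be non-negative and sum
#' to 1 within `1e-6`; they are renormalised to sum to 1 exactly. Larger
#' deviations are rejected rather than silently rescaled.
#'
#' @param material Character vector of component labels (unique).
#' @param volume_fraction Numeric vector of volume fractions.
#' @return A `composition` tibble.
#' @examples
#' composition(c("A", "B"), c(0.5, 0.5))
#' @export
composition <- function(material, volume_fraction) {
  if (length(material) != length(volume_fraction) || length(material) == 0) {
    stop_compactmix("composition",
                    "material and volume_fraction must be equal-length, non-empty.")
  }
  if (anyDuplicated(material)) {
    stop_compactmix("composition", "material labels must be unique.")
  }
  if (any(!is.finite(volume_fraction)) || any(volume_fraction < 0)) {
    stop_compactmix("composition", "volume fractions must be finite and >= 0.")
  }
  s <- sum(volume_fraction)
  if (abs(s - 1) > 1e-6) {
    stop_compactmix("composition", sprintf(
      "volume fractions must sum to 1 within 1e-6 (got %.8f).", s))
  }
  out <- tibble::tibble(material = as.character(material),
                        volume_fraction = volume_fraction / s)
  class(out) <- c("composition", class(out))
  out
}

#' Volume fractions from weight fractions and true densities
#'
#' Converts weight fractions \eqn{w_i} and true densities \eqn{\rho_i} into
#' volume fractions
#' \deqn{V_i = \frac{w_i/\rho_i}{\sum_j w_j/\rho_j},}
#' the proportion of true (skeletal) solid volume each component occupies.
#'
#' @param material Component labels.
#' @param weight_fraction Mass fractions, >= 0, summing to 1 within `1e-6`.
#' @param true_density True densities in g/cm^3, > 0.
#' @return A `composition` tibble carrying `weight_fraction` and
#'   `true_density` alongside the computed `volume_fraction`.
#' @examples
#' volume_fractions(c("A", "B"), c(0.5, 0.5), c(1, 2))
#' @export
volume_fractions <- function(material, weight_fraction, true_density) {
  if (length(weight_fraction) != length(true_density) ||
      length(material) != length(weight_fraction)) {
    stop_compactmix("composition", "inputs must have equal lengths.")
  }
  if (any(!is.finite(true_density)) || any(true_density <= 0)) {
    stop_compactmix("composition", "true densities must be positive.")
  }
  if (any(!is.finite(weight_fraction)) || any(weight_fraction < 0)) {
    stop_compactmix("composition", "weight fractions must be >= 0.")
  }
  if (abs(sum(weight_fraction) - 1) > 1e-6) {
    stop_compactmix("composition", "weight fractions must sum to 1 within 1e-6.")
  }
  v <- (weight_fraction / true_density) / sum(weight_fraction / true_density)
  out <- composition(material, v)
  out$weight_fraction <- weight_fraction
  out$true_density <- true_density
  out
}

#' True density of a powder mixture
#'
#' Combines component true densities by weight proportion assuming additive
#' specific volumes (the weight-harmonic mean):
#' \deqn{\rho_{mix} = 1 / \sum_i (w_i/\rho_i).}
#'
#' @param weight_fraction Mass fractions summing to 1 within `1e-6`.
#' @param true_density True densities, g/cm^3.
#' @return Mixture true density, g/cm^3.
#' @examples
#' mixture_true_density(c(0.5, 0.5), c(1, 2))  # 4/3
#' @export
mixture_true_density <- function(weight_fraction, true_density) {
  if (length(weight_fraction) != length(true_density)) {
    stop_compactmix("composition", "inputs must have equal lengths.")
  }
  if (any(!is.finite(true_density)) || any(true_density <= 0)) {
    stop_compactmix("composition", "true densities must be positive.")
  }
  if (any(weight_fraction < 0) || abs(sum(weight_fraction) - 1) > 1e-6) {
    stop_compactmix("composition", "weight fractions must be >= 0 and sum to 1.")
  }
  w <- weight_fraction / sum(weight_fraction)
  1 / sum(w / true_density)
}

# All weak compositions of n into m non-negative parts (stars and bars),
# returned as a C(n+m-1, m-1) x m integer matrix. Lexicographic in the first
# component descending, which keeps binary output in the familiar
# (n,0), (n-1,1), ..., (0,n) order.
enumerate_clusters <- function(n, m) {
  if (m == 1L) return(matrix(n, nrow = 1L))
  parts <- lapply(n:0, function(k1) {
    rest <- enumerate_clusters(n - k1, m - 1L)
    cbind(k1, rest, deparse.level = 0)
  })
  do.call(rbind, parts)
}

# log multinomial coefficient n! / prod(k_j!); exact-integer route for
# small n, log-gamma beyond (needed for the large-order asymptote).
lmultinom <- function(k) {
  n <- sum(k)
  if (n <= 20) {
    coefs <- choose(cumsum(k), k)  # product of binomials is exact here
    log(prod(coefs))
  } else {
    lgamma(n + 1) - sum(lgamma(k + 1))
  }
}

#' Cluster-type distribution for an interaction order
#'
#' Enumerates every cluster type of `order` particles drawn from the mixture
#' components (all weak compositions of the order into the number of
#' components) and computes, for each type, its multinomial probability under
#' random mixing,
#' \deqn{P(k) = \binom{n}{k_1,\dots,k_m}\prod_j V_j^{k_j},}
#' and its strength as the geometric mean of the member particles'
#' component strengths, \eqn{\prod_j \sigma_j^{k_j/n}}. Probabilities and
#' strengths are computed in log space so large orders stay finite; a cluster
#' containing at least one particle of a zero-strength component has cluster
#' strength 0.
#'
#' For a binary mixture this reduces to the binomial distribution over the
#' \eqn{n+1} contact types (for order 2: the classical A-A, A-B, B-B split).
#'
#' @param comp A [composition()] (or any data frame with `material` and
#'   `volume_fraction` columns).
#' @param strengths Component tensile strengths in MPa, aligned with the rows
#'   of `comp` (or a vector named by material).
#' @param order Number of particles in an interaction cluster (n >= 1).
#' @return A `cluster_distribution` tibble with one row per cluster type:
#'   one `k_<material>` count column per component, `multiplicity` (the
#'   multinomial coefficient), `probability`, and `cluster_strength` (MPa).
#'   Probabilities sum to 1.
#' @examples
#' cluster_distribution(composition(c("A", "B"), c(0.5, 0.5)),
#'                      strengths = c(10, 1), order = 2)
#' @export
cluster_distribution <- function(comp, strengths, order = 4) {
  check_order(order)
  comp <- as_composition(comp)
  strengths <- align_strengths(strengths, comp)
  m <- nrow(comp)
  V <- comp$volume_fraction
  K <- enumerate_clusters(as.integer(order), m)
  logV <- ifelse(V > 0, log(V), 0)     # k=0 terms contribute 0 either way
  logS <- ifelse(strengths > 0, log(strengths), 0)
  lcoef <- apply(K, 1L, lmultinom)
  # P = coef * prod V^k; zero whenever some k_j > 0 has V_j = 0
  zeroV <- K %*% (V == 0) > 0
  prob <- ifelse(zeroV, 0, exp(lcoef + K %*% logV))
  zeroS <- K %*% (strengths == 0) > 0
  strength <- ifelse(zeroS, 0, exp((K %*% logS) / order))
  counts <- tibble::as_tibble(as.data.frame(K),
                              .name_repair = ~ paste0("k_", comp$material))
  out <- dplyr::bind_cols(
    tibble::tibble(order = as.integer(order)),
    counts,
    tibble::tibble(multiplicity = round(exp(lcoef)),
                   probability = as.numeric(prob),
                   cluster_strength = as.numeric(strength)))
  class(out) <- c("cluster_distribution", class(out))
  out
}

#' Mixture tensile strength under the n-th order interaction model
#'
#' Predicts the tensile strength of a mixture as the expected cluster
#' strength over the cluster-type distribution of [cluster_distribution()]:
#' each interaction cluster of `order` particles forms with multinomial
#' probability given by the component volume fractions, and contributes the
#' geometric mean of its members' component strengths. For a binary mixture
#' this is
#' \deqn{\sigma_{mix} = \sum_{i=0}^{n} \binom{n}{i} V_A^{n-i} V_B^i
#'   \left(\sigma_A^{n-i}\sigma_B^i\right)^{1/n}.}
#'
#' Order 2 is the classical pairwise-contact model; the default order 4 is
#' the configuration found most accurate for pharmaceutical binary mixtures;
#' as the order grows the prediction approaches the power law (all-adhesive
#' geometric mixing).
#'
#' @inheritParams cluster_distribution
#' @return Predicted mixture tensile strength, MPa (scalar).
#' @examples
#' comp <- composition(c("A", "B"), c(0.5, 0.5))
#' interaction_predict(comp, strengths = c(10, 1), order = 4)
#' @export
interaction_predict <- function(comp, strengths, order = 4) {
  dist <- cluster_distribution(comp, strengths, order)
  sum(dist$probability * dist$cluster_strength)
}

#' Linear (arithmetic) mixing rule
#'
#' \eqn{\sigma_{mix} = \sum_i V_i \sigma_i}. Algebraically identical to the
#' second-order interaction model when adhesive contacts are assigned the
#' arithmetic mean of the cohesive strengths.
#'
#' @inheritParams cluster_distribution
#' @return Predicted mixture tensile strength, MPa.
#' @export
linear_rule <- function(comp, strengths) {
  comp <- as_composition(comp)
  strengths <- align_strengths(strengths, comp)
  sum(comp$volume_fraction * strengths)
}

#' Power law (geometric mixing rule)
#'
#' \eqn{\sigma_{mix} = \prod_i \sigma_i^{V_i}}: the all-adhesive limit in
#' which every contact strength is a Berthelot geometric mean. Returns 0 when
#' any component present in the mixture has zero strength (continuity as
#' \eqn{\sigma \to 0}).
#'
#' @inheritParams cluster_distribution
#' @return Predicted mixture tensile strength, MPa.
#' @export
power_law <- function(comp, strengths) {
  comp <- as_composition(comp)
  strengths <- align_strengths(strengths, comp)
  V <- comp$volume_fraction
  if (any(V > 0 & strengths == 0)) return(0)
  active <- V > 0
  exp(sum(V[active] * log(strengths[active])))
}

#' Mixture prediction by combining Ryshkewitch-Duckworth parameters
#'
#' Comparator rules that mix the pure-component R-D parameters first and
#' evaluate the exponential afterwards: \eqn{\sigma_{0,mix}} and
#' \eqn{k_{mix}} are each formed from the component values by either the
#' linear rule (L, volume-fraction-weighted arithmetic mean) or the power law
#' (P, volume-fraction-weighted geometric mean). The two-letter `variant`
#' names the rule for \eqn{\sigma_0} then the rule for \eqn{k}: e.g. `"LP"`
#' mixes \eqn{\sigma_0} linearly and \eqn{k} geometrically. The prediction at
#' porosity \eqn{\varepsilon} is \eqn{\sigma_{0,mix} e^{-k_{mix}\varepsilon}}.
#'
#' @param profiles A named list of `rd_fit` profiles (keyed by material), or
#'   a profile table as from [fit_rd_profiles()].
#' @param comp A [composition()].
#' @param porosity Porosities in `[0, 1)` at which to predict.
#' @param variant One of `"LL"`, `"LP"`, `"PL"`, `"PP"`.
#' @return Predicted tensile strengths, MPa, one per porosity.
#' @examples
#' profs <- list(A = rd_profile("A", 10, 8), B = rd_profile("B", 2, 5))
#' comp <- composition(c("A", "B"), c(0.5, 0.5))
#' rd_combination_predict(profs, comp, porosity = 0.2, variant = "PP")
#' @export
rd_combination_predict <- function(profiles, comp, porosity,
                                   variant = c("LL", "LP", "PL", "PP")) {
  if (length(variant) != 1 || !variant %in% c("LL", "LP", "PL", "PP")) {
    stop_compactmix("configuration",
                    "variant must be one of 'LL', 'LP', 'PL', 'PP'.")
  }
  comp <- as_composition(comp)
  profiles <- as_profile_list(profiles, comp$material)
  if (any(!is.finite(porosity)) || any(porosity < 0) || any(porosity >= 1)) {
    stop_compactmix("domain", "porosity must lie in [0, 1).")
  }
  V <- comp$volume_fraction
  s0 <- vapply(profiles[comp$material], function(p) p$sigma0, numeric(1))
  kk <- vapply(profiles[comp$material], function(p) p$k, numeric(1))
  mix <- function(x, rule) {
    if (rule == "L") sum(V * x) else exp(sum(V * log(x)))
  }
  s0_mix <- mix(s0, substr(variant, 1, 1))
  k_mix <- mix(kk, substr(variant, 2, 2))
  s0_mix * exp(-k_mix * porosity)
}

#' Predict a mixture compactibility profile over a porosity grid
#'
#' The porosity-matching contract at the heart of mixture prediction: at each
#' grid porosity, every pure component's strength is evaluated from its own
#' compactibility profile at that same porosity, and the chosen mixing model
#' is applied to those matched strengths. R-D-combination models (`rd-LL`
#' etc.) instead combine the profile parameters directly.
#'
#' @param profiles Named list of `rd_fit` profiles or a profile table.
#' @param comp A [composition()].
#' @param porosity Numeric grid of porosities in `[0, 1)`.
#' @param model One of `"interaction"`, `"linear"`, `"power"`, `"rd-LL"`,
#'   `"rd-LP"`, `"rd-PL"`, `"rd-PP"`; or a compound id like
#'   `"interaction-4"` fixing the order.
#' @param order Interaction order (used when `model = "interaction"`).
#' @return A `mixture_prediction` tibble: `porosity`, `tensile_strength`
#'   (MPa), `model`, `order` (NA for non-interaction models).
#' @examples
#' profs <- list(A = rd_profile("A", 10, 8), B = rd_profile("B", 2, 5))
#' comp <- composition(c("A", "B"), c(0.5, 0.5))
#' predict_mixture_profile(profs, comp, porosity = c(0.1, 0.2), model = "interaction")
#' @export
predict_mixture_profile <- function(profiles, comp, porosity,
                                    model = "interaction", order = 4) {
  spec <- parse_model_id(model, order)
  comp <- as_composition(comp)
  profiles <- as_profile_list(profiles, comp$material)
  if (length(porosity) == 0) {
    stop_compactmix("configuration", "porosity grid is empty.")
  }
  if (any(!is.finite(porosity)) || any(porosity < 0) || any(porosity >= 1)) {
    stop_compactmix("domain", "porosity grid must lie in [0, 1).")
  }
  if (spec$family == "rd") {
    sig <- rd_combination_predict(profiles, comp, porosity, spec$variant)
  } else {
    # evaluate each component at the SAME porosity, then mix
    smat <- vapply(comp$material,
                   function(m) predict(profiles[[m]], porosity),
                   numeric(length(porosity)))
    smat <- matrix(smat, nrow = length(porosity))
    mixer <- switch(spec$family,
                    interaction = function(s) interaction_predict(comp, s, spec$order),
                    linear = function(s) linear_rule(comp, s),
                    power = function(s) power_law(comp, s))
    sig <- vapply(seq_along(porosity), function(i) mixer(smat[i, ]), numeric(1))
  }
  out <- tibble::tibble(porosity = porosity, tensile_strength = sig,
                        model = spec$id,
                        order = if (spec$family == "interaction")
                          as.integer(spec$order) else NA_integer_)
  class(out) <- c("mixture_prediction", class(out))
  out
}

#' @export
autoplot.mixture_prediction <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$porosity, .data$tensile_strength,
                               colour = .data$model)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "porosity", y = "predicted tensile strength (MPa)")
}

# ---- model id handling -----------------------------------------------------

supported_models <- function() {
  c("interaction", "linear", "power", "rd-LL", "rd-LP", "rd-PL", "rd-PP")
}

# "interaction-4" -> family interaction, order 4; "rd-PP" -> family rd.
# Returns list(id, family, order, variant).
parse_model_id <- function(model, order = 4) {
  if (length(model) != 1 || !is.character(model)) {
    stop_compactmix("configuration", "model must be a single string.")
  }
  if (grepl("^interaction(-[0-9]+)?$", model)) {
    n <- if (model == "interaction") order else
      as.integer(sub("interaction-", "", model))
    check_order(n)
    return(list(id = paste0("interaction-", n), family = "interaction",
                order = n, variant = NA_character_))
  }
  if (model %in% c("linear", "power")) {
    return(list(id = model, family = model, order = NA_integer_,
                variant = NA_character_))
  }
  if (grepl("^rd-(LL|LP|PL|PP)$", model)) {
    return(list(id = model, family = "rd", order = NA_integer_,
                variant = sub("rd-", "", model)))
  }
  stop_compactmix("configuration", sprintf(
    "unknown model '%s'; supported: %s, or 'interaction-<n>'.",
    model, paste(supported_models(), collapse = ", ")))
}

check_order <- function(order) {
  if (length(order) != 1 || !is.finite(order) || order < 1 ||
      order != round(order)) {
    stop_compactmix("domain", "interaction order must be an integer >= 1.")
  }
  invisible(TRUE)
}

as_composition <- function(comp) {
  if (inherits(comp, "composition")) return(comp)
  if (is.data.frame(comp) &&
      all(c("material", "volume_fraction") %in% names(comp))) {
    return(composition(comp$material, comp$volume_fraction))
  }
  stop_compactmix("composition",
                  "expected a composition() or a data frame with material and volume_fraction.")
}

align_strengths <- function(strengths, comp) {
  if (!is.null(names(strengths))) {
    missing <- setdiff(comp$material, names(strengths))
    if (length(missing) > 0) {
      stop_compactmix("configuration", sprintf(
        "no strength supplied for component(s): %s",
        paste(missing, collapse = ", ")))
    }
    strengths <- strengths[comp$material]
  }
  if (length(strengths) != nrow(comp)) {
    stop_compactmix("configuration",
                    "strengths must align with the composition components.")
  }
  if (any(!is.finite(strengths)) || any(strengths < 0)) {
    stop_compactmix("domain", "strengths must be finite and >= 0.")
  }
  unname(strengths)
}

as_profile_list <- function(profiles, materials) {
  if (is.data.frame(profiles)) profiles <- profiles_from_table(profiles)
  if (inherits(profiles, "rd_fit")) profiles <- list(profiles)
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- vapply(profiles, function(p) p$material_id, character(1))
  }
  missing <- setdiff(materials, names(profiles))
  if (length(missing) > 0) {
    stop_compactmix("configuration", sprintf(
      "missing compactibility profile for: %s", paste(missing, collapse = ", ")))
  }
  profiles
}
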