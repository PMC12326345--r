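test_that("volume fractions follow the specific-volume rule", {
  vf <- volume_fractions(c("A", "B"), c(0.5, 0.5), c(1, 2))
  expect_equal(vf$volume_fraction, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # equal weights, equal densities -> equal volumes
  vf2 <- volume_fractions(c("A", "B", "C"), rep(1 / 3, 3), rep(1.4, 3))
  expect_equal(vf2$volume_fraction, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(volume_fractions("A", 1, 2.2)$volume_fraction, 1)
  expect_error(volume_fractions(c("A", "B"), c(0.5, 0.5), c(1, -2)),
               class = "compactmix_composition")
  expect_error(volume_fractions(c("A", "B"), c(0.5, 0.5), 1),
               class = "compactmix_composition")
  expect_error(volume_fractions(c("A", "B"), c(0.7, 0.5), c(1, 2)),
               class = "compactmix_composition")
})

test_that("mixture true density is the weight-harmonic mean", {
  expect_equal(mixture_true_density(c(0.5, 0.5), c(1, 2)), 4 / 3,
               tolerance = 1e-12)
  expect_equal(mixture_true_density(c(0.3, 0.7), c(1.6, 1.6)), 1.6,
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    w <- runif(3); w <- w / sum(w)
    rho <- runif(3, 0.8, 3)
    rmix <- mixture_true_density(w, rho)
    expect_gte(rmix, min(rho))
    expect_lte(rmix, max(rho))
  }
})

test_that("composition construction normalizes and validates", {
  c1 <- composition(c("A", "B"), c(0.5 + 2e-7, 0.5))
  expect_equal(sum(c1$volume_fraction), 1)
  expect_error(composition(c("A", "B"), c(0.6, 0.5)),
               class = "compactmix_composition")
  expect_error(composition(c("A", "A"), c(0.5, 0.5)),
               class = "compactmix_composition")
  expect_error(composition(c("A", "B"), c(1.2, -0.2)),
               class = "compactmix_composition")
})

test_that("cluster distribution has the right support, coefficients and mass", {
  comp <- composition(c("A", "B"), c(0.5, 0.5))
  d4 <- cluster_distribution(comp, c(10, 1), order = 4)
  expect_equal(nrow(d4), 5L)  # C(4+1, 1) compositions of 4 into 2 parts
  expect_equal(d4$multiplicity, c(1, 4, 6, 4, 1))
  expect_equal(sum(d4$probability), 1, tolerance = 1e-12)
  # cluster strengths are the geometric means (sigma_A^(k/n) sigma_B^((n-k)/n))
  expect_equal(d4$cluster_strength, 10^(d4$k_A / 4), tolerance = 1e-12)

  # printed cohesive fractions for equal-parts binaries
  d2 <- cluster_distribution(comp, c(10, 1), order = 2)
  pure2 <- d2$probability[d2$k_A == 0 | d2$k_B == 0]
  expect_equal(sum(pure2), 0.5, tolerance = 1e-12)
  d6 <- cluster_distribution(comp, c(10, 1), order = 6)
  pure6 <- d6$probability[d6$k_A == 0 | d6$k_B == 0]
  expect_equal(sum(pure6), 2 * 0.5^6, tolerance = 1e-12)

  # ternary support size: C(n+m-1, m-1)
  c3 <- composition(c("A", "B", "C"), c(0.2, 0.3, 0.5))
  d <- cluster_distribution(c3, c(1, 2, 3), order = 5)
  expect_equal(nrow(d), choose(5 + 2, 2))
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  expect_error(cluster_distribution(comp, c(10, 1), order = 0),
               class = "compactmix_domain")
})

test_that("cluster probabilities sum to 1 for large orders and m up to 4", {
  set.seed(11)
  for (i in 1:25) {
    m <- sample(2:4, 1)
    n <- sample(2:50, 1)
    v <- runif(m); v <- v / sum(v)
    comp <- composition(paste0("c", seq_len(m)), v)
    d <- cluster_distribution(comp, runif(m, 0.1, 20), order = n)
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  }
})

test_that("interaction prediction matches closed form and pure-component limits", {
  comp <- composition(c("A", "B"), c(0.5, 0.5))
  # frozen from the ordered-sequence oracle (also re-derived below)
  expect_equal(interaction_predict(comp, c(10, 1), 4), 3.723777,
               tolerance = 1e-6)
  expect_equal(interaction_predict(comp, c(10, 1), 4),
               oracle_interaction(c(0.5, 0.5), c(10, 1), 4),
               tolerance = 1e-13)
  # pure component, any order
  pureA <- composition(c("A", "B"), c(1, 0))
  for (n in c(1, 2, 4, 7)) {
    expect_equal(interaction_predict(pureA, c(7.7, 3.2), n), 7.7,
                 tolerance = 1e-12)
  }
  # equal strengths: probabilities integrate to the common value
  set.seed(5)
  for (i in 1:10) {
    v <- runif(1, 0.05, 0.95)
    comp2 <- composition(c("A", "B"), c(v, 1 - v))
    expect_equal(interaction_predict(comp2, c(4.2, 4.2), sample(1:12, 1)), 4.2,
                 tolerance = 1e-12)
  }
})

test_that("interaction prediction equals the ordered-sequence oracle", {
  set.seed(101)
  for (i in 1:40) {
    m <- sample(2:3, 1)
    n <- sample(1:8, 1)
    v <- runif(m); v <- v / sum(v)
    s <- runif(m, 0.1, 30)
    comp <- composition(paste0("c", seq_len(m)), v)
    expect_equal(interaction_predict(comp, s, n), oracle_interaction(v, s, n),
                 tolerance = 1e-12)
  }
})

test_that("linear rule and power law bracket the interaction family", {
  comp <- composition(c("A", "B"), c(0.5, 0.5))
  expect_equal(linear_rule(comp, c(10, 1)), 5.5)
  expect_equal(power_law(comp, c(10, 1)), sqrt(10), tolerance = 1e-12)
  expect_equal(linear_rule(composition(c("A", "B"), c(1, 0)), c(9, 2)), 9)
  expect_equal(power_law(composition(c("A", "B"), c(1, 0)), c(9, 2)), 9)

  set.seed(7)
  for (i in 1:30) {
    comp <- random_binary_comp()
    s <- runif(2, 0.05, 25)
    lin <- linear_rule(comp, s)
    pow <- power_law(comp, s)
    expect_lte(pow, lin + 1e-12)  # AM-GM
    for (n in c(2, 5, 9)) {
      ip <- interaction_predict(comp, s, n)
      expect_lte(ip, lin + 1e-12)
      expect_gte(ip, pow - 1e-12)
      expect_gte(ip, min(s) - 1e-12)
      expect_lte(ip, max(s) + 1e-12)
    }
  }
})

test_that("predictions strictly decrease with interaction order (rank order)", {
  set.seed(13)
  for (i in 1:50) {
    comp <- random_binary_comp()
    s <- runif(2, 0.1, 20)
    if (abs(s[1] - s[2]) < 1e-3) s[2] <- s[2] + 1
    preds <- vapply(2:10, function(n) interaction_predict(comp, s, n),
                    numeric(1))
    expect_true(all(diff(preds) < 0))
    expect_lt(preds[1], linear_rule(comp, s))
    expect_gt(preds[length(preds)], power_law(comp, s))
  }
})

test_that("large-order predictions approach the power law", {
  set.seed(17)
  for (i in 1:10) {
    comp <- random_binary_comp()
    s <- runif(2, 2, 6)  # moderate ratio: the n=200 gap scales with log-ratio^2
    pow <- power_law(comp, s)
    expect_lt(abs(interaction_predict(comp, s, 200) - pow) / pow, 1e-3)
  }
})

test_that("second order with arithmetic-mean adhesive strength is the linear rule", {
  set.seed(19)
  for (i in 1:25) {
    comp <- random_binary_comp()
    s <- runif(2, 0.1, 20)
    d <- cluster_distribution(comp, s, order = 2)
    # replace each cluster's geometric-mean strength by the arithmetic mean
    # of its members' component strengths
    arith <- (d$k_A * s[1] + d$k_B * s[2]) / 2
    expect_equal(sum(d$probability * arith), linear_rule(comp, s),
                 tolerance = 1e-14)
  }
})

test_that("zero-strength components behave continuously", {
  comp <- composition(c("A", "B"), c(0.5, 0.5))
  expect_equal(power_law(comp, c(10, 0)), 0)
  # only the pure-A cluster survives at order n: V_A^n * sigma_A
  for (n in c(2, 4)) {
    expect_equal(interaction_predict(comp, c(10, 0), n), 0.5^n * 10,
                 tolerance = 1e-12)
  }
  # continuity: sigma_B -> 0 approaches the exact-zero value (the gap decays
  # like sigma_B^(1/n), so the probe must sit deep in the tail)
  expect_equal(interaction_predict(comp, c(10, 1e-16), 4),
               interaction_predict(comp, c(10, 0), 4), tolerance = 1e-3)
})

test_that("predictions are invariant to component relabeling and zero padding", {
  set.seed(23)
  for (i in 1:15) {
    v <- runif(3); v <- v / sum(v)
    s <- runif(3, 0.1, 15)
    comp <- composition(c("A", "B", "C"), v)
    perm <- sample(3)
    comp_p <- composition(c("A", "B", "C")[perm], v[perm])
    n <- sample(1:7, 1)
    expect_equal(interaction_predict(comp, s, n),
                 interaction_predict(comp_p, s[perm], n), tolerance = 1e-12)
    expect_equal(linear_rule(comp, s), linear_rule(comp_p, s[perm]),
                 tolerance = 1e-12)
    expect_equal(power_law(comp, s), power_law(comp_p, s[perm]),
                 tolerance = 1e-12)
    # ternary with a vanished third component reduces to the binary model
    v2 <- c(v[1], v[2]) / (v[1] + v[2])
    tern <- composition(c("A", "B", "C"), c(v2, 0))
    bin <- composition(c("A", "B"), v2)
    expect_equal(interaction_predict(tern, s, n),
                 interaction_predict(bin, s[1:2], n), tolerance = 1e-12)
  }
})

test_that("R-D combination rules mix parameters as labeled", {
  profs <- list(A = rd_profile("A", 10, 8), B = rd_profile("B", 2, 5))
  comp <- composition(c("A", "B"), c(0.5, 0.5))
  expect_equal(rd_combination_predict(profs, comp, 0.2, "PP"),
               sqrt(20) * exp(-0.2 * sqrt(40)), tolerance = 1e-12)
  expect_equal(rd_combination_predict(profs, comp, 0.2, "LL"),
               6 * exp(-0.2 * 6.5), tolerance = 1e-12)
  expect_equal(rd_combination_predict(profs, comp, 0.2, "LP"),
               6 * exp(-0.2 * sqrt(40)), tolerance = 1e-12)
  expect_equal(rd_combination_predict(profs, comp, 0.2, "PL"),
               sqrt(20) * exp(-0.2 * 6.5), tolerance = 1e-12)
  # identical components: every variant returns the pure profile
  same <- list(A = rd_profile("A", 10, 8), B = rd_profile("B", 10, 8))
  for (v in c("LL", "LP", "PL", "PP")) {
    expect_equal(rd_combination_predict(same, comp, 0.15, v),
                 10 * exp(-8 * 0.15), tolerance = 1e-12)
  }
  # equal k: LL factorizes into the linear rule at each porosity
  eqk <- list(A = rd_profile("A", 10, 7), B = rd_profile("B", 3, 7))
  eps <- c(0.1, 0.25)
  expect_equal(rd_combination_predict(eqk, comp, eps, "LL"),
               0.5 * 10 * exp(-7 * eps) + 0.5 * 3 * exp(-7 * eps),
               tolerance = 1e-12)
  expect_error(rd_combination_predict(profs, comp, 0.2, "XX"),
               class = "compactmix_configuration")
})

test_that("mixture profile prediction matches components at the same porosity", {
  profs <- list(A = rd_profile("A", 10, 8), B = rd_profile("B", 2, 5))
  comp <- composition(c("A", "B"), c(0.5, 0.5))
  eps <- seq(0.1, 0.3, by = 0.05)
  pred <- predict_mixture_profile(profs, comp, eps, model = "interaction",
                                  order = 4)
  expect_equal(nrow(pred), length(eps))
  expect_equal(pred$model, rep("interaction-4", length(eps)))
  # re-derive each point from the matched component strengths
  manual <- vapply(eps, function(e) {
    interaction_predict(comp, c(10 * exp(-8 * e), 2 * exp(-5 * e)), 4)
  }, numeric(1))
  expect_equal(pred$tensile_strength, manual, tolerance = 1e-12)

  # where the component curves cross, every model agrees with the common value
  # 10 exp(-8 e) = 2 exp(-5 e) -> e = log(5)/3
  e_cross <- log(5) / 3
  s_common <- 10 * exp(-8 * e_cross)
  for (mid in c("interaction-4", "interaction-2", "linear", "power")) {
    p <- predict_mixture_profile(profs, comp, e_cross, model = mid)
    expect_equal(p$tensile_strength, s_common, tolerance = 1e-10)
  }

  # rank order across models on a single-porosity grid
  grid <- 0.15
  get1 <- function(mid) predict_mixture_profile(profs, comp, grid,
                                                model = mid)$tensile_strength
  expect_true(get1("linear") > get1("interaction-2"))
  expect_true(get1("interaction-2") > get1("interaction-4"))
  expect_true(get1("interaction-4") > get1("power"))

  expect_error(predict_mixture_profile(profs["A"], comp, grid),
               class = "compactmix_configuration")
  expect_error(predict_mixture_profile(profs, comp, numeric(0)),
               class = "compactmix_configuration")
  expect_error(predict_mixture_profile(profs, comp, 1.2),
               class = "compactmix_domain")
  expect_error(predict_mixture_profile(profs, comp, grid, model = "bogus"),
               class = "compactmix_configuration")
})
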