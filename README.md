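# compactmix

Predicting the tensile strength of compacted powder mixtures from
pure-component compactibility data.

## The problem

A tablet formulation is only viable if the compact reaches a usable
diametral tensile strength at the porosity the press achieves. Measuring
compactibility for every candidate blend is slow and material-hungry, so
formulation scientists want to *predict* a mixture's strength-porosity
profile from measurements on the pure ingredients alone. `compactmix`
implements an interaction-cluster model for that prediction, the classical
mixing rules it is compared against, and the supporting machinery: raw
tablet-measurement reduction, Ryshkewitch-Duckworth profile fitting,
RMSE-based model comparison, a seeded synthetic-data generator, a
formulation design-space screener and a command-line interface.

## The model

Each pure component's compactibility is the Ryshkewitch-Duckworth profile

    sigma(eps) = sigma0 * exp(-k * eps)

with `sigma0` the zero-porosity strength (MPa) and `k` the bonding-capacity
constant, fitted from tablet data via `eps = 1 - 4W/(pi D^2 t rho)` and
`sigma = 2F/(pi D t)`.

A mixture's strength at porosity `eps` is modelled as the expected strength
of a random cluster of `n` interacting particles (`n` = interaction order).
Cluster composition is multinomial in the component volume fractions
`V_j = (w_j/rho_j) / sum(w_i/rho_i)`, and a cluster with `k_j` particles of
component `j` has the geometric-mean strength `prod_j sigma_j(eps)^(k_j/n)`:

    sigma_mix = sum over {k : |k| = n} of
                multinom(n; k) * prod_j V_j^k_j * prod_j sigma_j^(k_j/n)

Order 2 is the classical pairwise-contact model; order 4 (the default) is
the configuration found most accurate for pharmaceutical binaries; as
`n -> infinity` the prediction approaches the power law
`prod_j sigma_j^V_j`, and the linear rule `sum_j V_j sigma_j` bounds the
family from above. Components are always evaluated at the *same* porosity
before mixing — that porosity matching is the core contract.

## Worked example

Simulate a two-component study (strong binder vs weak filler, 5%
multiplicative strength noise), fit profiles from the raw tablet table, and
ask which mixing model best explains mixture data generated by the
order-4 model:

```r
library(compactmix)

spec     <- generator_spec(noise_sd = 0.05)
tablets  <- generate_tablet_table(spec, seed = 11)
profiles <- tablets |> compact_points() |> fit_rd_profiles()
profiles
#> # A tibble: 2 × 8
#>   material sigma0_MPa     k eps_min eps_max n_points n_excluded     rss
#>   <chr>         <dbl> <dbl>   <dbl>   <dbl>    <int>      <int>   <dbl>
#> 1 strong        11.5   5.88   0.100     0.3       15          0 0.520
#> 2 weak           2.59 11.3    0.100     0.3       15          0 0.00194

sim  <- generate_mixture_dataset(spec, truth_model = "interaction",
                                 truth_order = 4, seed = 11)
cmpn <- evaluate_models(sim$data, sim$compositions,
                        profiles_from_table(profiles),
                        models = c("interaction-2", "interaction-4",
                                   "interaction-6", "linear", "power",
                                   "rd-PP"))
glance(cmpn)
#> # A tibble: 6 × 4
#>   model           rmse n_points  rank
#>   <chr>          <dbl>    <int> <int>
#> 1 interaction-4 0.0765       45     1
#> 2 interaction-6 0.108        45     2
#> 3 rd-PP         0.159        45     3
#> 4 interaction-2 0.231        45     4
#> 5 power         0.236        45     5
#> 6 linear        0.632        45     6
```

The generating model (order 4) attains the lowest pooled RMSE (0.077 MPa
over 45 measured points; fitted from noisy profiles, not the generating
parameters), and the ranking reproduces the characteristic ordering
linear > order 2 > order 4 > ... with the power law at the bottom of the
interaction family.

The cluster table behind a prediction is inspectable directly — for an
equal-parts binary at order 4 (strengths 10 and 1 MPa):

```r
cluster_distribution(composition(c("A", "B"), c(0.5, 0.5)),
                     strengths = c(10, 1), order = 4)
#> # A tibble: 5 × 6
#>   order   k_A   k_B multiplicity probability cluster_strength
#>   <int> <int> <int>        <dbl>       <dbl>            <dbl>
#> 1     4     4     0            1      0.0625            10
#> 2     4     3     1            4      0.25               5.62
#> 3     4     2     2            6      0.375              3.16
#> 4     4     1     3            4      0.25               1.78
#> 5     4     0     4            1      0.0625             1
```

whose probability-weighted strength is the order-4 prediction, 3.724 MPa.

A command-line wrapper (`inst/scripts/compactmix`) exposes the same
pipeline as subcommands `fit`, `predict`, `clusters`, `compare`, `simulate`
and `design-space` over plain CSV tables.

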