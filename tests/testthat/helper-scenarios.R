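# Shared scenario shorthands. The scenario definitions themselves live in
# tc_example_scenario(); sizes are discussed in the methods vignette.

recovery_scenario <- function(seed = 10L) tc_example_scenario("recovery", seed)
null_scenario <- function(seed = 20L) tc_example_scenario("null", seed)
modifier_scenario <- function(seed = 30L) tc_example_scenario("modifier", seed)

# Small generic dataset for plumbing tests.
small_sim <- function(seed = 3L, n_zctas = 10L, years = 2004:2009,
                      storms_per_year = 0.5, ...) {
  simulate_tc_data(tc_scenario(n_zctas = n_zctas, years = years,
                               storms_per_year = storms_per_year,
                               seed = seed, ...))
}
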