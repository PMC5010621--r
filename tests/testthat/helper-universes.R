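# Shared synthetic universes, built once per test run.

.univ_cache <- new.env()

cached_universe <- function(key, config, seed) {
  if (is.null(.univ_cache[[key]])) {
    .univ_cache[[key]] <- standardise_universe(
      simulate_universe(config, seed = seed))
  }
  .univ_cache[[key]]
}

# default desk-scale universe (400 areas, ~1,600 samples)
default_universe <- function() {
  cached_universe("default", sim_config(), seed = 101L)
}

# small universe without soil samples, for disease-model tests
area_universe <- function() {
  cached_universe("areas", sim_config(sample_density = c(0, 0, 0)),
                  seed = 202L)
}

# compact universe with samples, for joint-model tests
joint_universe <- function() {
  cached_universe("joint",
                  sim_config(nx = 15, ny = 10,
                             truth = list(field = list(range = 20))),
                  seed = 303L)
}
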