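# Shared study-condition simulations, memoized so several test files can
# reuse one realization.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .sim_cache)) assign(key, fn(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# default study conditions: slopes 0.0502 / 0.0328, 2000 genes, 2e6
# fragments per condition
default_sim <- function() {
  cached("default_sim", function() simulate_dataset(sim_config(seed = 101L)))
}

default_pipeline <- function() {
  cached("default_pipeline", function() {
    sim <- default_sim()
    suppressWarnings(suppressMessages(
      run_eskor_pipeline(sim$genes, sim$genome, sim$frags_unt, sim$frags_kd,
                         expr = sim$expr)))
  })
}

# matched null: identical slopes, no positional decay
null_sim <- function() {
  cached("null_sim", function() {
    simulate_dataset(sim_config(slope_kd = 0.0502, decay = 0, seed = 102L))
  })
}

null_pipeline <- function() {
  cached("null_pipeline", function() {
    sim <- null_sim()
    suppressWarnings(suppressMessages(
      run_eskor_pipeline(sim$genes, sim$genome, sim$frags_unt, sim$frags_kd,
                         expr = sim$expr)))
  })
}
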