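# The three-archetype study underlying the plan-quality and ordering tests
# is expensive (nine influence scenarios and three solves per archetype),
# so it is computed once per test session and shared across test blocks.
# Influence matrices are dropped after evaluation to bound memory.
study_runs <- local({
  cache <- new.env(parent = emptyenv())
  function(archetype) {
    if (is.null(cache[[archetype]])) {
      res <- run_experiment(default_experiment_config(archetype))
      res$influences <- NULL
      gc(verbose = FALSE)
      cache[[archetype]] <- res
    }
    cache[[archetype]]
  }
})

study_archetypes <- c("wraparound", "abutting", "inferior_extension")

nominal_metrics <- function(res) {
  m <- res$report$scenario_metrics
  m[m$scenario == "nominal", ]
}
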