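# Expensive reference trajectories are shared across test files through a
# lazily filled cache (the simulator is deterministic, so reuse is safe).
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

ref_params <- function(...) model_parameters(...)

ref_line <- function(line) {
  cached(paste0("line_", line), run_line(line, model_parameters()))
}

ref_upshift <- function(Ki_I = 0.3, k_GFP = 0.1) {
  cached(sprintf("ups_%g_%g", Ki_I, k_GFP),
         simulate_with_upshift(model_parameters(Ki_I = Ki_I, k_GFP = k_GFP)))
}

ref_t05 <- function(Ki_I = 0.3, k_GFP = 0.1) {
  cached(sprintf("t05_%g_%g", Ki_I, k_GFP),
         as.numeric(response_time(model_parameters(Ki_I = Ki_I,
                                                   k_GFP = k_GFP))))
}

# deterministic pseudo-random states for property checks
random_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    AcylACP = stats::runif(n, 0, 5), FA = stats::runif(n, 0, 2000),
    N = stats::runif(n, 0, 5), nutr = stats::runif(n),
    lim = stats::runif(n), ppGpp = stats::runif(n, 0, 1000),
    rib = stats::runif(n, 0, 1.5), I = stats::runif(n),
    GFP = stats::runif(n)
  )
}
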