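# Shared synthetic worlds, built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

noiseless_params <- function(seed = 11, ...) {
  truth_params(seed = seed, rain_rate = 0,
               noise_sd = list(flux = 0, o3 = 0, temp = 0), ...)
}

# 20-day noiseless world with deposition + conductance applied to truth GPP.
clean_world <- function() {
  memo("clean_world", {
    w <- simulate_dataset(20, noiseless_params())
    tab <- w$obs
    tab$GPP <- w$truth$GPP
    tab <- add_deposition(tab)
    w$cond <- add_conductance(tab)
    w$tab <- tab
    w
  })
}

# Default-condition full pipeline run (noisy, 62 days).
default_run <- function() {
  memo("default_run", suppressWarnings(run_pipeline(run_config(days = 62,
                                                               seed = 1))))
}

# Parameter-recovery ensemble: full pipeline on 20 seeded noisy seasons.
recovery_runs <- function() {
  memo("recovery_runs", lapply(1:20, function(s) {
    res <- suppressWarnings(run_pipeline(run_config(days = 62, seed = s)))
    fits <- res$fits[res$fits$converged, ]
    list(g0 = stats::median(fits$g0), g1 = stats::median(fits$g1),
         ustar = res$ustar$threshold, reliable = res$ustar$reliable,
         e0 = res$partition$e0,
         rref = stats::median(res$partition$rref_windows$rref))
  }))
}
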