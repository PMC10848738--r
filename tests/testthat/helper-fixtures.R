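# Shared fixtures, built in code.

# small synthetic study (8 years) for the expensive fitting paths
toy_config <- function(seed = 42, n_years = 8, obs_noise_sd = 0) {
  synthetic_config(n_years = n_years, seed = seed, obs_noise_sd = obs_noise_sd)
}

toy_study <- function(seed = 42, n_years = 8, obs_noise_sd = 0) {
  cfg <- toy_config(seed, n_years, obs_noise_sd)
  env <- gen_environment(cfg)
  anomalies <- gen_anomalies(env, cfg)
  observations <- gen_observations(cfg, anomalies)
  list(cfg = cfg, env = env, anomalies = anomalies,
    observations = observations)
}

# hand-built design with one or two blocks of iid columns (no env plumbing)
manual_design <- function(m, block_sizes, seed = 1, beta = NULL,
                          noise_sd = 0.2) {
  set.seed(seed)
  p <- sum(block_sizes)
  X <- matrix(stats::rnorm(m * p), m, p)
  fac <- rep(LETTERS[seq_along(block_sizes)], block_sizes)
  colnames(X) <- paste0(fac, "_m", unlist(lapply(block_sizes, seq_len)))
  if (is.null(beta)) beta <- numeric(p)
  y <- drop(X %*% beta) + stats::rnorm(m, 0, noise_sd)
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  structure(
    list(
      X = sweep(sweep(X, 2, center), 2, scl, "/"), X_raw = X, y = y,
      years = seq_len(m), factor = fac,
      cycle_month = unlist(lapply(block_sizes, seq_len)),
      center = center, scale = scl, factors = unique(fac)
    ),
    class = "factor_design"
  )
}
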