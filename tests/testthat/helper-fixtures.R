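# shared fixtures for the suite

# a balanced 2 x 4 factorial frame
make_factorial <- function(n_per_cell = 6, env_effect = 0, month_effect = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  env <- factor(rep(c("sunny", "shaded"), each = 4 * n_per_cell),
                levels = c("sunny", "shaded"))
  month <- factor(rep(rep(1:4, each = n_per_cell), 2))
  y <- rnorm(length(env)) +
    env_effect * (env == "shaded") +
    month_effect * as.integer(month)
  data.frame(y = y, env = env, month = month)
}

# one synthetic day table that qc_integrate() accepts
make_day_samples <- function(values, component = "GHI", I_E = 1000,
                             date = "d1") {
  n <- length(values)
  data.frame(
    date = date,
    decimal_hour = (seq_len(n) - 1) / 12,
    component = component,
    value_wm2 = values,
    I_E = rep_len(I_E, n),
    stringsAsFactors = FALSE
  )
}
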