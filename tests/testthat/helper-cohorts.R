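# Shared fixtures, built in code.

# A no-deficit configuration: patients drawn from the control distribution.
null_config <- function() {
  cohort_config(
    deficit_profiles = list(SV = c(), NFV = c(), LV = c()),
    latent_shifts = list(SV = c(0, 0), NFV = c(0, 0), LV = c(0, 0)),
    cpm_p2_r = 0)
}

# Small control table with independent covariates and outcomes.
flat_controls <- function(n = 28, seed = 42) {
  audbat:::with_seed(seed, {
    df <- data.frame(subject_id = sprintf("C%02d", 1:n), group = "control",
                     age = round(rnorm(n, 62, 8)),
                     cpm = round(rnorm(n, 32, 3)))
    for (task in battery_task_ids()) df[[task]] <- rnorm(n, 10, 2)
    df
  })
}
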