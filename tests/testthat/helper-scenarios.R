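# Shared fixtures, built in code at test time.

# one bright population positive for FAPa and CD26, no artefacts
clean_scenario <- function(n = 5000, seed = 42L, doublet_rate = 0,
                           dead_fraction = 0, ...) {
  scenario_config(
    populations = list(population_template("fc", c("FAPa", "CD26"))),
    abundance = data.frame(tumour_type = "4T1", day = 7,
                           population = "fc", fraction = 1),
    doublet_rate = doublet_rate, dead_fraction = dead_fraction,
    events_per_sample = n, seed = seed, ...)
}

# fully deterministic: no noise anywhere
noise_free_scenario <- function(n = 100, seed = 7L, ...) {
  scenario_config(
    populations = list(population_template("fc", c("FAPa", "CD26"),
                                           level_cv = 0)),
    abundance = data.frame(tumour_type = "4T1", day = 7,
                           population = "fc", fraction = 1),
    autofluorescence_sd = 0, doublet_rate = 0, dead_fraction = 0,
    scatter_cv = 0, events_per_sample = n, seed = seed, ...)
}

random_event_table <- function(n = 50, panel = default_panel()) {
  m <- matrix(stats::rexp(n * nrow(panel), rate = 1e-3), n, nrow(panel),
              dimnames = list(NULL, panel$detector))
  event_table(m, panel, sample_meta("rt", "4T1", 7, "rep1"))
}

# random valid spillover matrix with off-diagonals below `max_off`
random_spillover <- function(channels, max_off = 0.3) {
  k <- length(channels)
  s <- matrix(stats::runif(k * k, 0, max_off), k, k)
  diag(s) <- 1
  spillover_matrix(s, channels)
}
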