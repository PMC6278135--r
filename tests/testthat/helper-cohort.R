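# Small cohort configurations reused across tests.
small_config <- function(seed = 1, ...) {
  cohort_config(
    n_pfa = 12, n_pfb = 6, n_controls = 4,
    n_probes_total = 4400, n_sex_probes = 150,
    n_island_probes = 800, n_marker_probes = 60,
    seed = seed, ...
  )
}

# Gene-panel-only cohort: no probes, so generation is instant.
panel_config <- function(n_pfa = 90, n_pfb = 33, seed = 1, ...) {
  cohort_config(
    n_pfa = n_pfa, n_pfb = n_pfb, n_controls = 0,
    n_probes_total = 0, n_sex_probes = 0, n_island_probes = 0,
    n_marker_probes = 0, seed = seed, ...
  )
}
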