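# Shared fixtures, generated once per test session.

.fixtures <- new.env(parent = emptyenv())

default_case <- function() {
  if (is.null(.fixtures$case)) {
    .fixtures$cfg_gen <- insilico_config()
    .fixtures$case <- generate_insilico_case(.fixtures$cfg_gen)
  }
  list(frames = .fixtures$case, truth = .fixtures$cfg_gen)
}

# two-frame fully passive series from a known truth (for constitutive and
# landscape tests); ED at 2 kPa
passive_case <- function(params = guccione_params(1, 19.13, 10.67, 12.76),
                         geometry = lv_geometry(20, 10, 60),
                         pressures = c(0.33, 2.00)) {
  generate_insilico_case(insilico_config(
    params = params, geometry = geometry,
    pressures = pressures, at = rep(0, length(pressures))))
}

table1_params <- function() guccione_params(1, 19.13, 10.67, 12.76)

# log-spacing of the default alpha grid (one grid cell, as a ratio)
alpha_cell_ratio <- function(cfg = sweep_config()) {
  exp(mean(diff(log(cfg$alpha_grid))))
}
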