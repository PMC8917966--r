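# Shared fixtures: the representative device, its bending model, and the
# nondimensional groups of the reference delivery case (0.5 mA, square
# 50 um channel, atmospheric initial pressure, V0* = 0.9162).

t2_dev <- table2_device()
t2_model <- bending_plate_model(t2_dev)

t2_op <- function(i_mA = 0.5) {
  operating_conditions(i = i_mA * 1e-3, V0star = 0.9162)
}

fig_groups <- function(i_mA = 0.5) {
  compute_groups(t2_dev, t2_op(i_mA))
}

# lighter output grid for property loops (accuracy set by rtol, not grid)
fast_settings <- solver_settings(n_intervals = 2000L, n_layer = 800L)

# groups with prescribed Mstar, everything else from the reference case
groups_with_M <- function(Mstar, V0star = 0.9162, P0star = 0.101325) {
  nondimensional_groups(P0star = P0star, V0star = V0star, Mstar = Mstar,
                        Gprime0 = gprime0(t2_dev))
}
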