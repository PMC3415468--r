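# Second-order relay neuron: low-threshold T-type calcium current + leak.
# A minimal thalamic membrane built from the T-current and leak of the
# Rubin & Terman (2004, J Comput Neurosci 16:211-235) thalamocortical cell
# as used by Guo et al. (2008, J Neurophysiol 99:1477-1492); the same
# T+leak skeleton underlies the inferior-olive subthreshold oscillation
# model of Manor et al. (1997, J Neurophysiol 77:2736-2752).
# States: v (membrane voltage, mV), h (T-channel inactivation gate, [0,1]).
# Units: mV, ms, uA/cm2, mS/cm2, uF/cm2 throughout.
#
# dv/dt = (-I_T - I_L + I_ext - s(t) * (v - v_rev)) / C_m
#   I_T  = g_T * p_inf(v)^2 * h * (v - E_T)     (activation instantaneous)
#   I_L  = g_L * (v - E_L)
# dh/dt = phi_h * (h_inf(v) - h) / tau_h(v)
#   p_inf(v) = 1 / (1 + exp(-(v - p_vhalf) / p_k))        rising sigmoid
#   h_inf(v) = 1 / (1 + exp( (v - h_vhalf) / h_k))        falling sigmoid
#   tau_h(v) = tau_h_base + tau_h_amp * exp(-(v - tau_h_vhalf) / tau_h_k)

C_m: 1.0          # uF/cm2, membrane capacitance (Rubin & Terman 2004, TC cell)
g_T: 5.0          # mS/cm2, maximal T-type Ca conductance (Rubin & Terman 2004)
E_T: 0.0          # mV, Ca reversal used by the source TC model (Rubin & Terman 2004)
g_L: 0.05         # mS/cm2, leak conductance (Rubin & Terman 2004)
E_L: -70.0        # mV, leak reversal (Rubin & Terman 2004)
I_ext: 0.0        # uA/cm2, constant external current (resting operating point)
v_rev: -85.0      # mV, inhibitory synaptic reversal for the modulating
                  # conductance (GABA-A, GPi->thalamus; Rubin & Terman 2004)
phi_h: 1.0        # dimensionless temperature correction on the gate

p_vhalf: -60.0    # mV, T activation half-voltage (Rubin & Terman 2004)
p_k: 6.2          # mV, T activation slope (Rubin & Terman 2004)
h_vhalf: -84.0    # mV, T inactivation half-voltage (Rubin & Terman 2004)
h_k: 4.0          # mV, T inactivation slope (Rubin & Terman 2004)
tau_h_base: 28.0  # ms   (Rubin & Terman 2004: tau_r = 28 + exp(-(v+25)/10.5))
tau_h_amp: 1.0    # ms
tau_h_vhalf: -25.0 # mV
tau_h_k: 10.5     # mV

# Simulation/detection defaults for this model (package operating point).
detect_level: -40.0  # mV; low-threshold Ca spikes peak near -28..-21 mV
                     # (E_T = 0 caps the upstroke), so an upward crossing of
                     # -40 mV is the spike surrogate for this model.
relay_window: 25.0   # ms; relay window Delta covering the spike latency of
                     # near-threshold responses in this model
S0_default: 0.1      # mS/cm2, modulating DC offset at the baseline operating point
S1_default: 0.02     # mS/cm2, modulating amplitude (small-signal regime)
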