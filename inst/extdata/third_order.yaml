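# Third-order thalamocortical relay neuron: leak + fast sodium + potassium
# + low-threshold T-type calcium current.  Structure and kinetics follow the
# reduced thalamocortical cell of Rubin & Terman (2004, J Comput Neurosci
# 16:211-235), itself a simplification of Sohal & Huguenard-type thalamic
# models, as used by Guo et al. (2008, J Neurophysiol 99:1477-1492).
# States: v (mV), h (Na inactivation, also gating the K current through the
# n = 0.75*(1-h) reduction), r (T-channel inactivation).
# Units: mV, ms, uA/cm2, mS/cm2, uF/cm2.
#
# dv/dt = (-I_L - I_Na - I_K - I_T + I_ext - s(t) * (v - v_rev)) / C_m
#   I_L  = g_L * (v - E_L)
#   I_Na = g_Na * m_inf(v)^3 * h * (v - E_Na)    (m instantaneous)
#   I_K  = g_K * (k_n * (1 - h))^4 * (v - E_K)
#   I_T  = g_T * p_inf(v)^2 * r * (v - E_T)      (p instantaneous)
# dh/dt = phi_h * (h_inf(v) - h) / tau_h(v),  tau_h = 1/(a_h(v) + b_h(v))
# dr/dt = phi_r * (r_inf(v) - r) / tau_r(v)

C_m: 1.0          # uF/cm2 (Rubin & Terman 2004)
g_L: 0.05         # mS/cm2 (Rubin & Terman 2004)
E_L: -70.0        # mV (Rubin & Terman 2004)
g_Na: 3.0         # mS/cm2 (Rubin & Terman 2004; deliberately small Na)
E_Na: 50.0        # mV (Rubin & Terman 2004)
g_K: 5.0          # mS/cm2 (Rubin & Terman 2004)
E_K: -90.0        # mV (Rubin & Terman 2004)
g_T: 2.0          # mS/cm2; within the published range for reduced TC cells.
                  # Chosen so that a delta pulse delivered in the
                  # hyperpolarized state elicits a multi-spike rebound burst
                  # (at 5 mS/cm2 the Ca envelope saturates near 0 mV and
                  # carries a single Na spike instead of a burst).
E_T: 0.0          # mV (Rubin & Terman 2004)
v_rev: -85.0      # mV, inhibitory synaptic reversal (Rubin & Terman 2004)
phi_h: 1.0        # dimensionless
phi_r: 1.0        # dimensionless
k_n: 0.75         # K-gate reduction n = k_n*(1-h) (Rubin & Terman 2004)

m_vhalf: -37.0    # mV (Rubin & Terman 2004)
m_k: 7.0          # mV
h_vhalf: -41.0    # mV (falling sigmoid)
h_k: 4.0          # mV
a_h_amp: 0.128    # 1/ms, tau_h = 1/(a_h + b_h), a_h = a_h_amp*exp(-(v - a_h_vhalf)/a_h_k)
a_h_vhalf: -46.0  # mV
a_h_k: 18.0       # mV
b_h_amp: 4.0      # 1/ms, b_h = b_h_amp/(1 + exp(-(v - b_h_vhalf)/b_h_k))
b_h_vhalf: -23.0  # mV
b_h_k: 5.0        # mV
p_vhalf: -60.0    # mV (Rubin & Terman 2004)
p_k: 6.2          # mV
r_vhalf: -84.0    # mV (falling sigmoid)
r_k: 4.0          # mV
tau_r_base: 28.0  # ms (Rubin & Terman 2004: tau_r = 28 + exp(-(v+25)/10.5))
tau_r_amp: 1.0    # ms
tau_r_vhalf: -25.0 # mV
tau_r_k: 10.5     # mV

# Operating points: the external current selects the firing regime.
I_ext_bursting: -0.6  # uA/cm2; hyperpolarized state, T de-inactivated,
                      # pulses elicit multi-spike rebound bursts
I_ext_tonic: 0.3      # uA/cm2; depolarized relay mode, pulses elicit a
                      # single Na spike (chosen below the range where a
                      # second depolarized equilibrium appears)
I_ext: -0.6           # default = bursting operating point

# Simulation/detection defaults for this model.
detect_level: -25.0   # mV; with g_Na = 3 the Na spikes peak just above 0 mV
                      # and later burst spikelets peak near -25..-5 mV.
relay_window: 40.0   # ms; relay window Delta covering the spike latency of
                     # near-threshold responses in this model
S0_default: 0.05      # mS/cm2
S1_default: 0.02      # mS/cm2
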