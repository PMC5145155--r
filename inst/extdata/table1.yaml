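# Canonical parameter configuration of the DA neuron model: the published
# table values plus the calibrated constants of the Ca2+ subsystem and Ih
# reversal (see the methods vignette for the calibration rationale).
# Units: mV, ms, mS/cm^2, uF/cm^2, uM.
c_m: 1
gbar_ca: 2.5
gbar_kca: 7.8
gbar_k: 1
gbar_sna: 0.13
gbar_na: 50
gbar_dr: 2
g_l: 0.18
g_h: 0
e_ca: 50
e_k: -90
e_na: 55
e_l: -35
e_h: -20
beta_ca: 0.05
r: 20
z: 2
faraday: 96485
p_ca: 6.5e-05
k_sk: 1.5
mg: 0.5
m_e: 0.062
ca_leak_frac: 0.1
vhalf_ca: -41.4
k_ca: 3
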