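# Lu-177 electron emission scheme (replaceable default).
# Approximate transcription in the style of ICRP Publication 107: three main
# beta branches (endpoint keV, branching probability) and the principal
# internal-conversion electron lines (energy keV, intensity per decay).
# Photons and Auger electrons are intentionally absent (neglected by design).
# half_life_h: 159.528
[beta]
endpoint_keV,probability
177.0,0.116
385.3,0.090
498.3,0.794
[ic]
energy_keV,intensity
47.6,0.0980
101.7,0.0138
110.7,0.0031
143.1,0.0204
196.1,0.0058
206.1,0.0058
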