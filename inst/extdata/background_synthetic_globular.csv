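# SYNTHETIC background composition of well-folded globular proteins.
# Constructed in-package as a stand-in: the curated background sets used by
# composition-profiling web services (ordered-protein selections of the PDB,
# curated disordered sets, proteome-wide distributions) are not
# redistributable here. Frequencies are normalised on load.
code,freq
A,0.088
C,0.015
D,0.059
E,0.064
F,0.042
G,0.073
H,0.022
I,0.057
K,0.058
L,0.090
M,0.022
N,0.044
P,0.045
Q,0.037
R,0.049
S,0.060
T,0.055
V,0.070
W,0.014
Y,0.036
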