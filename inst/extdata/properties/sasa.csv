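# Solvent-accessible surface area in the tripeptide G-X-G (nm^2)
# Standard amino-acid index values as tabulated in the sequence
# autocovariance / autocorrelation descriptor literature.
amino_acid,value
A,1.181
R,2.560
N,1.655
D,1.587
C,1.461
Q,1.932
E,1.862
G,0.881
H,2.025
I,1.810
L,1.931
K,2.258
M,2.034
F,2.228
P,1.468
S,1.298
T,1.525
W,2.663
Y,2.368
V,1.645
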