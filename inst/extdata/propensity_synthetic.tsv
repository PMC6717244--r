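aa	propensity
A	0.9805
C	0.952
D	0.8711
E	1.0953
F	0.9885
G	1.2869
H	0.9359
I	0.9604
K	1.0493
L	1.0818
M	1.0229
N	0.9788
P	1.0513
Q	1.0049
R	1.0564
S	0.9285
T	1.0362
V	0.9589
W	1.0774
Y	1.0441
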