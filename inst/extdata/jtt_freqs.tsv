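aa	freq
A	0.0767479232520768
R	0.0516909483090517
N	0.0426449573550427
D	0.0515439484560515
C	0.0198029801970198
Q	0.0407519592480408
E	0.0618299381700618
G	0.0731519268480732
H	0.0229439770560229
I	0.0537609462390538
L	0.0919039080960919
K	0.0586759413240587
M	0.0238259761740238
F	0.0401259598740401
P	0.0509009490990509
S	0.0687649312350688
T	0.0585649414350586
W	0.0142609857390143
Y	0.0321019678980321
V	0.066004933995066
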