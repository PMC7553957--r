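# p53risk amino-acid property table, schema_version=1
# hbond_class: donor_only {K,R,W}; acceptor_only {E,D}; both {H,N,Q,S,T,Y}; neither otherwise
# polarity_class: default charge/polarity partition; histidine placed polar_uncharged
aa	hbond_class	polarity_class
A	neither	nonpolar
C	neither	nonpolar
D	acceptor_only	negative
E	acceptor_only	negative
F	neither	nonpolar
G	neither	nonpolar
H	both	polar_uncharged
I	neither	nonpolar
K	donor_only	positive
L	neither	nonpolar
M	neither	nonpolar
N	both	polar_uncharged
P	neither	nonpolar
Q	both	polar_uncharged
R	donor_only	positive
S	both	polar_uncharged
T	both	polar_uncharged
V	neither	nonpolar
W	donor_only	nonpolar
Y	both	polar_uncharged
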