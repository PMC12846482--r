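class	count
A/G	562792
C/T	561959
A/C	207819
A/T	252865
C/G	146809
G/T	206979
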