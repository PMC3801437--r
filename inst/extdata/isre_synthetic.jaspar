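>ISRE_synthetic synthetic stand-in for the canonical ISRE (consensus AGTTTCANTTTC)
A [ 70  5  5  5  5  5 60 25 10  5  5 10 ]
C [ 10  5  5  5  5 85 10 25 10  5  5 70 ]
G [ 10 85  5  5  5  5 15 25 10  5  5 10 ]
T [ 10  5 85 85 85  5 15 25 70 85 85 10 ]
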