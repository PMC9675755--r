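>PPRE_synthetic
A  [ 28.0000 28.0000 6.6667 6.6667 28.0000 6.6667 6.6667 6.6667 6.6667 28.0000 28.0000 28.0000 6.6667 6.6667 6.6667 6.6667 28.0000 ]
C  [ 6.6667 6.6667 28.0000 6.6667 6.6667 6.6667 6.6667 6.6667 28.0000 6.6667 6.6667 6.6667 6.6667 6.6667 6.6667 28.0000 6.6667 ]
G  [ 6.6667 6.6667 6.6667 6.6667 6.6667 28.0000 28.0000 6.6667 6.6667 6.6667 6.6667 6.6667 28.0000 28.0000 6.6667 6.6667 6.6667 ]
T  [ 6.6667 6.6667 6.6667 28.0000 6.6667 6.6667 6.6667 28.0000 6.6667 6.6667 6.6667 6.6667 6.6667 6.6667 28.0000 6.6667 6.6667 ]
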