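chr1	0	2000	low_mappability
chr2	500000	505000	high_signal_artifact
chr4	1995000	2000000	low_mappability
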