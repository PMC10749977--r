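set	mean_size
CD	28106
FS-1	150
FS-2	848
FS-3	699
FI-1	102
FI-2	11
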