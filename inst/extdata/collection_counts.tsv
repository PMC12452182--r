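stratum	riboswitches	genes
Pseudomonadota	17605	8493198
all	70892	19940848
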