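trinucleotide	genome	exome
ACA	0.036	0.03186225
ACC	0.024	0.03061275
ACG	0.024	0.03061275
ACT	0.036	0.03186225
ATA	0.054	0.03316275
ATC	0.036	0.03186225
ATG	0.036	0.03186225
ATT	0.054	0.03316275
CCA	0.024	0.03061275
CCC	0.016	0.02941225
CCG	0.016	0.02941225
CCT	0.024	0.03061275
CTA	0.036	0.03186225
CTC	0.024	0.03061275
CTG	0.024	0.03061275
CTT	0.036	0.03186225
GCA	0.024	0.03061275
GCC	0.016	0.02941225
GCG	0.016	0.02941225
GCT	0.024	0.03061275
GTA	0.036	0.03186225
GTC	0.024	0.03061275
GTG	0.024	0.03061275
GTT	0.036	0.03186225
TCA	0.036	0.03186225
TCC	0.024	0.03061275
TCG	0.024	0.03061275
TCT	0.036	0.03186225
TTA	0.054	0.03316275
TTC	0.036	0.03186225
TTG	0.036	0.03186225
TTT	0.054	0.03316275
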