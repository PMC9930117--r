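OC(=O)c1ccc(Nc2ccccc2)cc1 EX-ACT1
OC(=O)c1ccc(Nc2ccc(Cl)cc2)cc1 EX-ACT2
OC(=O)c1ccc(Nc2ccc(OC)cc2)cc1C EX-ACT3
OC(=O)c1ccc(Nc2ccc(O)c(C)c2)cc1 EX-ACT4
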