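>Q9LED1 Pru p 3 mature chain, synthetic verified reconstruction
ITCGQVSSALAPCIPYVRGGGAVPPACCNGIRNVNNLARTTPDRQAACNCLKQLSASVPG
VNPNNAAALPGKCGVSIPYKISASTNCATVK
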