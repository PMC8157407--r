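# H-bond donor/acceptor atom definitions (version 1).
# role<TAB>SMARTS ; first matched atom of each hit is the feature atom.
# Donors: any N-H or O-H (amide N-H included).
# Acceptors: N/O excluding amide nitrogen, nitro oxygens/nitrogen,
# pyrrole-type aromatic N-H and quaternary nitrogen.
donor	[#7;!H0]
donor	[#8;!H0]
acceptor	[#7;!$([#7][CX3]=[OX1]);!$([nX3H1]);!$([NX3](=[OX1])[OX1]);!$([NX3](=[OX1])=[OX1]);!$([#7X4])]
acceptor	[#8;!$([OX1]=[NX3]);!$([OX1]~[NX3]~[OX1]);!$([OX2][NX3]=[OX1])]
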