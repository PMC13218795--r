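# Fixture gene panel: meiosis / gametogenesis / infertility-associated genes
SPO11
MEI1
REC114
ANKRD31
DMC1
CNTD1
MLH3
SYCE1
SYCE2
SYCE3
SYCP1
SYCP2
SYCP3
MEIKIN
MEIOB
STAG3
HORMAD1
HORMAD2
MSH4
MSH5
TEX11
TEX12
TEX15
MCM8
MCM9
FANCM
PRDM9
HFM1
SHOC1
MND1
PSMC3IP
TLE6
PADI6
NLRP2
NLRP5
TUBB8
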