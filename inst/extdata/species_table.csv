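species,formula,volume_A3,source
H2O,H2O,30.01,volume from density 0.997 g/cm3 at 25 C
D2O,D2O,30.11,volume from density 1.1044 g/cm3 at 25 C
silicon,Si,20.02,diamond-cubic cell a = 5.431 A with 8 atoms
silicon_oxide,SiO2,45.35,amorphous native oxide at 2.20 g/cm3
pc_headgroup,C10H18NO8P,319,phosphatidylcholine headgroup fragment volume
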