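scenario,state,energy_eV,tolerance_eV
duplex_thermal,GC,0.00,0.02
duplex_thermal,TS1,0.60,0.02
duplex_thermal,G_minus_C_plus,0.55,0.02
duplex_thermal,GstarCstar,0.60,0.02
helicaseN1_thermal,GC,0.00,0.02
helicaseN1_thermal,TS1,0.57,0.02
helicaseN1_thermal,G_minus_C_plus,0.49,0.02
helicaseN1_thermal,GstarCstar,0.55,0.02
helicaseN_thermal,GC,0.00,0.02
helicaseN_thermal,TS1,1.24,0.02
helicaseN_thermal,G_minus_C_plus,1.22,0.02
helicaseN_thermal,TS2,1.68,0.02
helicaseN_thermal,GstarCstar,1.68,0.02
n624a_thermal,GC,0.00,0.02
n624a_thermal,TS1,0.86,0.02
n624a_thermal,G_minus_C_plus,0.82,0.02
n624a_thermal,GstarCstar,1.18,0.02
duplex_frozen,GC,0.00,0.02
duplex_frozen,TS1,0.77,0.02
duplex_frozen,G_minus_C_plus,0.61,0.02
duplex_frozen,TS2,1.31,0.02
duplex_frozen,GstarCstar,1.13,0.02
helicaseN_frozen,GC,0.00,0.02
helicaseN_frozen,TS1,1.38,0.02
helicaseN_frozen,G_minus_C_plus,1.35,0.02
helicaseN_frozen,G_plus_C_minus,1.93,0.02
helicaseN_frozen,TS2,2.76,0.02
helicaseN_frozen,GstarCstar,1.78,0.02
n624a_frozen,GC,0.00,0.02
n624a_frozen,TS1,1.23,0.02
n624a_frozen,G_minus_C_plus,1.19,0.02
n624a_frozen,G_plus_C_minus,2.04,0.02
n624a_frozen,TS2,2.42,0.02
n624a_frozen,GstarCstar,1.69,0.02
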