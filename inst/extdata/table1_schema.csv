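name,kind,preference,domain_type,domain
Coating,nominal,none,set,1;2;3
Tablet_press,numeric,none,set,1;2
Compression_force,numeric,none,set,6;12;18
Tablet_mass,numeric,none,range,516;568
Hardness,numeric,none,range,11;297
Crushing_strength,numeric,none,range,11;619
Friability,numeric,none,range,0;10.1
Avicel_102,numeric,none,set,0;12.7;47
Avicel_101,numeric,none,set,0;12.7
Mannitol,numeric,none,set,0;34.3
Tablettose_80,numeric,none,set,0;34.3
Ludipress_LCE,numeric,none,set,0;34.3
Arbocel_P290,numeric,none,set,0;47
Sorbitol,numeric,none,set,0;34.3
Povidone_K30,numeric,none,set,0;34.3
StarLac,numeric,none,set,0;34.3
Starch_1500,numeric,none,set,0;43.8
CaHPO4xH2O,numeric,none,set,0;34.3
CaHPO4,numeric,none,set,0;34.3
Vivapur_200,numeric,none,set,0;34.3
Avicel_CE015,numeric,none,set,0;34.3
Macrogol_6000,numeric,none,set,0;34.3
Kollidon_CL,numeric,none,set,0;9.5
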