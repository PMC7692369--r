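formulation,Coating,Tablet_press,Compression_force,Tablet_mass,Hardness,Crushing_strength,Friability,Avicel_102,Avicel_101,Mannitol,Tablettose_80,Ludipress_LCE,Arbocel_P290,Sorbitol,Povidone_K30,StarLac,Starch_1500,CaHPO4xH2O,CaHPO4,Vivapur_200,Avicel_CE015,Macrogol_6000,Kollidon_CL,f2
1,1,1,6,559,63,92,2.30,12.7,0,34.3,0,0,0,0,0,0,0,0,0,0,0,0,9.5,59.4
2,1,1,6,548,66,96,3.10,0,12.7,34.3,0,0,0,0,0,0,0,0,0,0,0,0,9.5,56.3
3,1,1,6,557,111,163,4.20,0,12.7,0,0,0,0,0,0,0,0,0,0,0,34.3,0,9.5,35.7
4,1,1,6,558,96,140,0.50,47,0,0,0,0,0,0,0,0,0,0,0,0,0,0,9.5,37.5
5,1,1,6,562,41,58,0.00,12.7,0,0,34.3,0,0,0,0,0,0,0,0,0,0,0,9.5,38.7
6,1,1,6,557,45,67,2.40,12.7,0,0,0,34.3,0,0,0,0,0,0,0,0,0,0,9.5,35.9
7,1,1,6,562,105,153,0.60,0,0,0,0,0,47,0,0,0,0,0,0,0,0,0,9.5,40.9
8,1,1,6,559,76,111,0.40,12.7,0,0,0,0,0,34.3,0,0,0,0,0,0,0,0,9.5,59.4
9,1,1,6,555,55,80,0.70,12.7,0,0,0,0,0,0,34.3,0,0,0,0,0,0,0,9.5,56.3
10,1,1,6,565,36,52,2.30,12.7,0,0,0,0,0,0,0,34.3,0,0,0,0,0,0,9.5,35.7
11,1,1,6,566,26,38,3.40,12.7,0,0,0,0,0,0,0,0,43.8,0,0,0,0,0,0,37.5
12,1,1,6,559,40,58,1.20,12.7,0,0,0,0,0,0,0,0,0,34.3,0,0,0,0,9.5,38.7
13,1,1,6,560,39,57,0.90,12.7,0,0,0,0,0,0,0,0,0,0,34.3,0,0,0,9.5,35.9
14,1,1,6,562,40,59,0.70,12.7,0,0,0,0,0,0,0,0,0,0,0,34.3,0,0,9.5,40.9
15,1,1,6,550,40,58,0.40,12.7,0,0,0,0,0,0,0,0,0,0,0,0,34.3,0,9.5,59.4
16,1,1,6,555,40,58,0.60,12.7,0,0,0,0,0,0,0,0,0,0,0,0,0,34.3,9.5,55.9
17,1,1,12,549,91,134,1.10,12.7,0,34.3,0,0,0,0,0,0,0,0,0,0,0,0,9.5,50.7
18,1,1,12,545,79,115,0.90,0,12.7,34.3,0,0,0,0,0,0,0,0,0,0,0,0,9.5,63.5
19,1,1,12,554,248,363,0.90,0,12.7,0,0,0,0,0,0,0,0,0,0,0,34.3,0,9.5,48.3
20,1,1,12,566,229,335,0.40,47,0,0,0,0,0,0,0,0,0,0,0,0,0,0,9.5,58.7
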