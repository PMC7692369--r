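class,rule,attribute,relation,threshold
1,1,Coating_2,=,0
1,1,Tablet_mass,<=,553.1
1,1,Crushing_strength,>=,68.8
1,1,Avicel_102,>=,12.7
1,2,Coating_1,=,1
1,2,Compression_force,>,6
1,2,Tablet_mass,<=,563.3
1,2,Hardness,>=,42.4
1,2,Avicel_101,=,0
1,3,Coating_1,=,1
1,3,Compression_force,>,6
1,3,Hardness,>=,49.2
1,3,Vivapur_200,=,0
1,3,Avicel_101,=,0
1,3,Povidone_K30,=,0
1,4,Coating_1,=,1
1,4,Compression_force,>,6
1,4,Hardness,>=,42.4
1,4,Povidone_K30,=,0
1,4,Mannitol,=,0
1,5,Coating_1,=,1
1,5,Compression_force,>,6
1,5,Crushing_strength,>=,102.5
1,5,Vivapur_200,=,0
1,5,StarLac,=,0
1,6,Coating_1,=,1
1,6,Hardness,>=,105.8
1,6,Avicel_101,=,0
1,7,Coating_1,=,1
1,7,Compression_force,>,6
1,7,Hardness,>=,105
1,8,Hardness,>,111.9
1,8,Crushing_strength,>,163.6
1,9,Coating_2,=,0
1,9,Crushing_strength,>=,180.8
1,10,Coating_2,=,0
1,10,Hardness,>=,107
1,11,Coating_1,=,1
1,11,Tablet_mass,<=,556.4
1,11,Friability,<=,1.6
1,12,Coating_1,=,1
1,12,Tablet_mass,<=,554.1
1,12,Friability,<=,1.1
1,13,Coating_1,=,1
1,13,Tablet_press,=,2
1,13,Hardness,>=,49.2
1,14,Coating_1,=,1
1,14,Compression_force,>,6
1,14,Tablet_mass,<=,561.5
1,14,Hardness,>=,49.2
1,14,Vivapur_200,=,0
1,14,Avicel_101,=,0
1,15,Coating_1,=,1
1,15,Compression_force,>,6
1,15,Hardness,>,42.4
1,15,Povidone_K30,=,0
1,16,Hardness,>=,148.9
1,16,Vivapur_200,=,0
1,17,Coating_1,=,1
1,17,Tablet_mass,<=,554.1
1,17,Avicel_102,>=,12.7
1,18,Coating_1,=,1
1,18,Compression_force,>,6
1,18,Vivapur_200,=,0
1,18,Avicel_101,=,0
1,18,Povidone_K30,=,0
1,18,StarLac,=,0
1,19,Coating_1,=,1
1,19,Compression_force,>,6
1,19,Hardness,>=,49.2
1,19,Vivapur_200,=,0
1,19,StarLac,=,0
1,19,Mannitol,=,0
1,20,Coating_2,=,0
1,20,Crushing_strength,>=,163.6
2,1,Tablet_press,=,2
2,1,Crushing_strength,<=,97.8
2,2,Coating_1,=,0
2,2,Compression_force,<,18
2,2,Crushing_strength,<=,158.3
2,3,Coating_1,=,0
2,3,Compression_force,<,18
2,3,Tablettose_80,=,0
2,4,Coating_1,=,0
2,4,Compression_force,<,18
2,4,Crushing_strength,<=,133.1
2,5,Coating_1,=,0
2,5,Tablet_press,=,2
2,5,Arbocel_P290,=,0
2,6,Crushing_strength,<=,68.1
2,6,Kollidon_CL,>=,9.5
2,7,Coating_1,=,0
2,7,Compression_force,<,18
2,7,Avicel_CE015,=,0
2,8,Compression_force,=,6
2,8,Crushing_strength,<=,72
2,9,Coating_1,=,0
2,9,Compression_force,<=,12
2,10,Tablet_press,=,2
2,10,Hardness,<=,48.8
2,11,Tablet_press,=,2
2,11,Hardness,<=,60.1
2,12,Coating_1,=,0
2,12,Compression_force,<,18
2,12,Tablet_mass,<,558
2,13,Coating_1,=,0
2,13,Tablet_press,=,2
2,13,Hardness,<=,84.5
2,14,Coating_1,=,0
2,14,Compression_force,<,18
2,14,Crushing_strength,<=,90.9
2,15,Compression_force,<,18
2,15,Crushing_strength,<=,67.3
2,16,Coating_2,=,1
2,17,Coating_1,=,0
2,17,Tablet_press,=,2
2,17,Crushing_strength,<=,158.3
2,18,Coating_1,=,0
2,18,Tablet_press,=,2
2,18,Crushing_strength,<=,138
2,19,Compression_force,<,18
2,19,Crushing_strength,<=,68.1
2,20,Coating_1,=,0
2,20,Tablet_press,=,2
2,20,Crushing_strength,<=,148.5
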