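id,name,category,tl,biomass,pb,cb,ee,ee_fixed,is_homeotherm
1,Large phytoplankton,producer,1.00,45.753,215.00,,0.980,FALSE,FALSE
2,Small phytoplankton,producer,1.00,6.230,215.00,,0.945,FALSE,FALSE
3,Micro-zooplankton,consumer,2.00,16.219,150.00,428.57,0.900,TRUE,FALSE
4,Large copepods,consumer,2.25,6.552,15.00,60.00,0.744,FALSE,FALSE
5,Small copepods,consumer,2.35,26.443,37.00,148.00,0.419,FALSE,FALSE
6,Small invertebrate larvae,consumer,2.35,4.813,37.00,148.00,0.573,FALSE,FALSE
7,Pteropods,consumer,2.53,0.272,15.00,50.00,0.759,FALSE,FALSE
8,Pelagic amphipods,consumer,2.65,0.662,14.00,56.00,0.734,FALSE,FALSE
9,Pelagic shrimp,consumer,3.27,18.939,3.00,12.00,0.885,FALSE,FALSE
10,Other macro-zooplankton,consumer,2.88,6.309,10.00,40.00,0.726,FALSE,FALSE
11,Small jellyfish (net-feeders),consumer,2.40,1.671,45.00,150.00,0.021,FALSE,FALSE
12,Small jellyfish (carnivores),consumer,3.48,0.054,20.00,66.67,0.023,FALSE,FALSE
13,Large jellyfish,consumer,3.08,0.101,15.00,60.00,0.079,FALSE,FALSE
14,Pyrosomes,consumer,2.08,15.976,45.00,150.00,0.001,FALSE,FALSE
15,E. pacifica,consumer,2.30,32.294,6.00,24.00,0.932,FALSE,FALSE
16,T. spinifera,consumer,2.30,10.234,7.00,28.00,0.799,FALSE,FALSE
17,Small cephalopod aggregate,consumer,3.63,2.640,3.00,12.00,0.850,TRUE,FALSE
18,Cephalopod humboldt,consumer,4.36,0.005,2.75,11.00,0.969,FALSE,FALSE
19,Smelt aggregate,consumer,3.65,7.383,1.80,7.20,0.821,FALSE,FALSE
20,Shad,consumer,3.34,2.081,1.13,4.53,0.900,TRUE,FALSE
21,Sardine,consumer,3.11,1.841,1.13,4.53,0.966,FALSE,FALSE
22,Herring,consumer,3.17,4.099,1.80,7.20,0.943,FALSE,FALSE
23,Anchovy,consumer,3.19,3.038,1.80,7.20,0.860,FALSE,FALSE
24,Saury,consumer,3.75,0.130,1.13,4.53,0.775,FALSE,FALSE
25,Coho yearling,consumer,4.28,0.222,1.80,7.20,0.933,FALSE,FALSE
26,Chinook yearling spring-run,consumer,4.20,0.110,1.13,4.53,0.881,FALSE,FALSE
27,Chinook yearling fall-run,consumer,4.24,0.080,1.13,4.53,0.834,FALSE,FALSE
28,Chinook subyearling fall-run early,consumer,3.94,0.015,1.80,7.20,0.841,FALSE,FALSE
29,Chinook subyearling fall-run late,consumer,4.19,0.094,1.80,7.20,0.820,FALSE,FALSE
30,Other Chinook yearling,consumer,4.31,0.014,1.13,4.53,0.956,FALSE,FALSE
31,Other Chinook subyearling,consumer,4.07,0.057,1.80,7.20,0.961,FALSE,FALSE
32,Other juvenile salmon,consumer,3.46,0.028,1.80,7.20,0.855,FALSE,FALSE
33,Mesopelagic fish aggregate,consumer,3.36,1.245,1.75,7.00,0.850,TRUE,FALSE
34,Planktivorous rockfish,consumer,3.76,6.420,0.13,1.25,0.952,FALSE,FALSE
35,Coho,consumer,4.17,0.230,1.80,10.59,0.739,FALSE,FALSE
36,Chinook,consumer,4.07,0.112,0.75,4.41,0.892,FALSE,FALSE
37,Other salmon aggregate,consumer,3.98,0.019,1.90,11.18,0.756,FALSE,FALSE
38,Shark aggregate,consumer,4.73,0.017,0.20,3.33,0.788,FALSE,FALSE
39,Jack mackerel,consumer,3.64,21.395,0.23,2.30,0.103,FALSE,FALSE
40,Pacific mackerel,consumer,3.49,0.857,0.76,7.60,0.848,FALSE,FALSE
41,Piscivorous rockfish,consumer,3.88,3.072,0.17,1.72,0.980,FALSE,FALSE
42,Dogfish aggregate,consumer,4.21,3.475,0.20,2.50,0.272,FALSE,FALSE
43,Hake,consumer,3.65,18.500,0.35,3.54,0.987,FALSE,FALSE
44,Tuna aggregate,consumer,4.29,0.200,0.30,3.00,0.893,FALSE,FALSE
45,Sablefish,consumer,4.16,1.787,0.23,2.30,0.952,FALSE,FALSE
46,Hexagrammidae (lingcod greenling),consumer,4.43,0.722,0.30,3.00,0.905,FALSE,FALSE
47,Flatfish (water-column feeders),consumer,4.29,3.797,0.28,1.38,0.817,FALSE,FALSE
48,Skates & rays,consumer,3.71,2.769,0.23,2.30,0.266,FALSE,FALSE
49,Misc. small benthic fishes,consumer,3.33,8.900,0.40,4.00,0.900,TRUE,FALSE
50,Benthivorous rockfish,consumer,3.67,7.987,0.07,0.70,0.811,FALSE,FALSE
51,Gadidae (cod haddock pollock),consumer,3.48,0.120,0.35,3.50,0.838,FALSE,FALSE
52,Flatfish (benthic feeders),consumer,3.16,11.878,0.30,3.00,0.684,FALSE,FALSE
53,Flatfish (small),consumer,3.45,7.968,0.38,1.90,0.919,FALSE,FALSE
54,Grenadier,consumer,3.62,1.206,0.20,1.00,0.066,FALSE,FALSE
55,Juvenile rockfish,consumer,3.51,1.202,2.70,10.80,0.930,FALSE,FALSE
56,Juvenile fish (other),consumer,3.26,5.991,2.70,10.80,0.735,FALSE,FALSE
57,Juvenile fish (chondrichthyes),consumer,3.44,0.535,2.70,10.80,0.850,TRUE,FALSE
58,Infauna,consumer,2.00,80.000,4.50,18.00,0.973,FALSE,FALSE
59,Pandalus spp.,consumer,2.91,14.257,3.00,12.00,0.903,FALSE,FALSE
60,Other epibenthic shrimp (Caridea),consumer,2.81,12.950,4.20,16.80,0.850,TRUE,FALSE
61,Mysids,consumer,2.83,2.637,22.00,110.00,0.850,TRUE,FALSE
62,Echinoderms,consumer,2.07,21.361,1.21,6.05,0.850,TRUE,FALSE
63,Benthic amphipods isopods and cumaceans,consumer,2.05,7.158,21.50,107.50,0.850,TRUE,FALSE
64,Bivalves,consumer,2.03,64.450,1.30,6.50,0.850,TRUE,FALSE
65,Misc. epifauna (suspension feeders),consumer,2.14,3.828,7.40,37.00,0.850,TRUE,FALSE
66,Dungeness crab,consumer,3.27,5.109,1.50,6.00,0.952,FALSE,FALSE
67,Tanner crab,consumer,2.99,0.869,1.00,4.00,0.939,FALSE,FALSE
68,Misc. epifauna (carnivorous),consumer,2.67,31.550,3.00,15.00,0.850,TRUE,FALSE
69,Sooty shearwaters,consumer,4.31,0.017,0.10,73.00,0.014,FALSE,TRUE
70,Common murre,consumer,4.37,0.015,0.17,72.00,0.210,FALSE,TRUE
71,Gulls & terns,consumer,3.79,0.001,0.17,73.00,0.774,FALSE,TRUE
72,Alcids,consumer,3.90,0.001,0.17,110.00,0.084,FALSE,TRUE
73,Large pelagic seabirds,consumer,4.08,0.001,0.07,75.00,0.128,FALSE,TRUE
74,Other pelagic seabirds,consumer,4.29,0.001,0.10,73.00,0.046,FALSE,TRUE
75,Coastal seabirds (divers),consumer,4.29,0.001,0.16,73.00,0.218,FALSE,TRUE
76,Storm-petrels,consumer,3.86,0.0001,0.12,144.00,0.072,FALSE,TRUE
77,Gray whales,consumer,3.72,0.146,0.06,8.90,0.002,FALSE,TRUE
78,Baleen whales,consumer,3.69,0.572,0.04,7.60,0.002,FALSE,TRUE
79,Small pinnipeds,consumer,4.55,0.024,0.08,8.30,0.034,FALSE,TRUE
80,Sea lions,consumer,4.64,0.049,0.07,24.00,0.279,FALSE,TRUE
81,Northern elephant seals,consumer,4.49,0.062,0.07,24.00,0.219,FALSE,TRUE
82,Small toothed whales,consumer,4.44,0.072,0.10,25.80,0.112,FALSE,TRUE
83,Large toothed whales,consumer,4.57,0.067,0.05,6.61,0.003,FALSE,TRUE
84,Other killer whales,consumer,4.94,0.0004,0.03,11.16,0.000,FALSE,TRUE
85,Southern resident killer whales,consumer,5.13,0.005,0.03,11.16,0.000,FALSE,TRUE
86,Invertebrate eggs,detritus,1.00,0.00002,0.00,0.00,0.225,FALSE,FALSE
87,Fish eggs,detritus,1.00,1.906,0.00,0.00,0.421,FALSE,FALSE
88,Pelagic detritus,detritus,1.00,10.000,0.00,0.00,0.525,FALSE,FALSE
89,Fishery offal,detritus,1.00,5.000,0.00,0.00,0.684,FALSE,FALSE
90,Benthic detritus,detritus,1.00,10.000,0.00,0.00,0.885,FALSE,FALSE
91,Dredge,fleet,3.04,,,,,FALSE,FALSE
92,Hook & line,fleet,5.16,,,,,FALSE,FALSE
93,Other gear,fleet,4.57,,,,,FALSE,FALSE
94,Net,fleet,4.34,,,,,FALSE,FALSE
95,Pot & trap,fleet,4.53,,,,,FALSE,FALSE
96,Trolling,fleet,5.23,,,,,FALSE,FALSE
97,Trawl (non-shrimp),fleet,4.67,,,,,FALSE,FALSE
98,Shrimp trawls,fleet,3.97,,,,,FALSE,FALSE
99,Recreational fishery,fleet,5.07,,,,,FALSE,FALSE
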