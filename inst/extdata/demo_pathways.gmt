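demo_glycolysis	toy glycolysis/gluconeogenesis set	C00031	C00085	C00103	C00186	C00022	C00074	C00197	C00118	C00111
demo_tca	toy TCA cycle set	C00042	C00122	C00149	C00158	C00026	C00036	C00022
demo_purine	toy purine metabolism set	C00020	C00008	C00002	C00144	C00035	C00130	C00361	C00262	C00385	C00366	C00147	C00242	C00013
demo_pyrimidine	toy pyrimidine metabolism set	C00105	C00055	C00106	C00380	C00178
demo_amino_acid	toy amino acid metabolism set	C00025	C00064	C00049	C00041	C00037	C00065	C00300	C00245
demo_pentose_phosphate	toy pentose phosphate set	C00117	C05382	C00279	C00085	C00118
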