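id	name	formula	monoisotopic_mass
C00031	D-Glucose	C6H12O6	180.06338808
C00085	D-Fructose-6-phosphate	C6H13O9P	260.02971897
C00103	D-Glucose-1-phosphate	C6H13O9P	260.02971897
C00329	D-Glucosamine	C6H13NO5	179.07937250
C00117	D-Ribose-5-phosphate	C5H11O8P	230.01915429
C00186	L-Lactate	C3H6O3	90.03169404
C00022	Pyruvate	C3H4O3	88.01604398
C00042	Succinate	C4H6O4	118.02660866
C00122	Fumarate	C4H4O4	116.01095860
C00149	L-Malate	C4H6O5	134.02152328
C00158	Citrate	C6H8O7	192.02700258
C00026	2-Oxoglutarate	C5H6O5	146.02152328
C00036	Oxaloacetate	C4H4O5	132.00587322
C00025	L-Glutamate	C5H9NO4	147.05315776
C00064	L-Glutamine	C5H10N2O3	146.06914218
C00049	L-Aspartate	C4H7NO4	133.03750770
C00041	L-Alanine	C3H7NO2	89.04767846
C00037	Glycine	C2H5NO2	75.03202840
C00065	L-Serine	C3H7NO3	105.04259308
C00020	AMP	C10H14N5O7P	347.06308481
C00008	ADP	C10H15N5O10P2	427.02941570
C00002	ATP	C10H16N5O13P3	506.99574659
C00144	GMP	C10H14N5O8P	363.05799943
C00035	GDP	C10H15N5O11P2	443.02433032
C00105	UMP	C9H13N2O9P	324.03586699
C00055	CMP	C9H14N3O8P	323.05185141
C00130	IMP	C10H13N4O8P	348.04710039
C00361	dGDP	C10H15N5O10P2	427.02941570
C00262	Hypoxanthine	C5H4N4O	136.03851078
C00385	Xanthine	C5H4N4O2	152.03342540
C00366	Urate	C5H4N4O3	168.02834002
C00147	Adenine	C5H5N5	135.05449520
C00242	Guanine	C5H5N5O	151.04940982
C00106	Uracil	C4H4N2O2	112.02727738
C00380	Cytosine	C4H5N3O	111.04326180
C00178	Thymine	C5H6N2O2	126.04292744
C00170	5-Methylthioadenosine	C11H15N5O3S	297.08956053
C01598	Melatonin	C13H16N2O2	232.12117774
C00093	sn-Glycerol-3-phosphate	C3H9O6P	172.01367499
C00013	Diphosphate	H4O7P2	177.94322646
C00074	Phosphoenolpyruvate	C3H5O6P	167.98237487
C00197	3-Phospho-D-glycerate	C3H7O7P	185.99293955
C00118	D-Glyceraldehyde-3-phosphate	C3H7O6P	169.99802493
C00111	Glycerone-phosphate	C3H7O6P	169.99802493
C05382	Sedoheptulose-7-phosphate	C7H15O10P	290.04028365
C00279	D-Erythrose-4-phosphate	C4H9O7P	200.00858961
C00003	NAD	C21H27N7O14P2	663.10912256
C00051	Glutathione	C10H17N3O6S	307.08380643
C00245	Taurine	C2H7NO3S	125.01466425
C00300	Creatine	C4H9N3O2	131.06947654
C00318	L-Carnitine	C7H15NO3	161.10519332
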