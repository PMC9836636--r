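family	species	bins	i_mean	i_max	nn_species	dnn
Gryllacrididae	Apotrechus bilobus	ADF4059:3	0.31	0.46	Eugryllacris elongata	14.88
Gryllacrididae	Capnogryllacris melanocrania	ADF2751:1;AEJ4972:1;ADF2750:2;AEJ9445:2	3.21	5.01	Eugryllacris elongata	16.4
Gryllacrididae	Eugryllacris elongata	AEK0366:1;ADF4811:5	3.63	10.84	Apotrechus bilobus	14.88
Gryllacrididae	Homogryllacris anelytra	ADF3866:3	0.83	1.09	Phryganogryllacris xiai	17.42
Gryllacrididae	Melaneremus fuscoterminatus	ADF2959:1;ADF2960:1	14.73	14.73	Melaneremus laticeps	3.78
Gryllacrididae	Melaneremus laticeps	ADF2961:4	0.08	0.15	Melaneremus fuscoterminatus	3.78
Gryllacrididae	Metriogryllacris permodesta	ADF4959:1	N/A	N/A	Phryganogryllacris xiai	18.4
Gryllacrididae	Phryganogryllacris superangulata	ADF3568:5	0.15	0.31	Capnogryllacris melanocrania	18.92
Gryllacrididae	Phryganogryllacris xiai	ADF3457:1	N/A	N/A	Homogryllacris anelytra	17.42
Rhaphidophoridae	Diestramima austrosinensis	ADE4649:6	0.3	0.61	Diestramima brevis	5.39
Rhaphidophoridae	Diestramima brevis	AEJ2460:5	0.37	0.93	Diestramima austrosinensis	5.39
Rhaphidophoridae	Gymnaetoides testaceus	AEJ5191:3	1.45	2.18	Tachycines meditationis	11.39
Rhaphidophoridae	Microtachycines elongatus	AEJ2738:2	0.62	0.62	Tachycines meditationis	11.75
Rhaphidophoridae	Tachycines meditationis	AEJ6894:1;AEK0279:2;AEJ9615:4	1.77	3.31	Gymnaetoides testaceus	11.39
Tettigoniidae	Atlanticus interval	ADE2184:3	0.72	1.08	Holochlora venusta	19.38
Tettigoniidae	Conocephalus bidentatus	ADB6577:1	N/A	N/A	Conocephalus maculatus	18.31
Tettigoniidae	Conocephalus gladiatus	ADE4649:1;ACD8581:17	1.06	2.18	Conocephalus maculatus	16.97
Tettigoniidae	Conocephalus maculatus	ACD2116:1;ADB5579:2	3.62	5.43	Conocephalus gladiatus	16.97
Tettigoniidae	Conocephalus melaenus	ACD4634:20	0.1	0.31	Conocephalus gladiatus	17.65
Tettigoniidae	Deflorita deflorita	ADB3725:14	0.79	2.67	Hemielimaea chinensis	16.35
Tettigoniidae	Ducetia japonica	ACD7324:47	1.23	2.67	Kuwayamaea brachyptera	14.3
Tettigoniidae	Elimaea annamensis	ADE1944:9	0.46	1.55	Elimaea terminalis	6.98
Tettigoniidae	Elimaea cheni	ADB3480:13	0.09	0.46	Elimaea nanpingensis	9.69
Tettigoniidae	Elimaea nanpingensis	ADB3475:12	0.06	0.17	Elimaea cheni	9.69
Tettigoniidae	Elimaea terminalis	ADB3392:3;ADB3394:3	6.35	10.68	Elimaea annamensis	6.98
Tettigoniidae	Euconocephalus nasutus	ACD6726:2	1.39	1.39	Ruspolia dubia	14.22
Tettigoniidae	Euxiphidiopsis capricercus	ADE2467:1	N/A	N/A	Gampsocleis sinensis	18.21
Tettigoniidae	Gampsocleis sinensis	AAY1322:58	0.87	2.03	Euxiphidiopsis capricercus	18.21
Tettigoniidae	Grigoriora cheni	ADE0541:7	0.79	1.39	Sinocyrtaspis brachycerca	13.2
Tettigoniidae	Hemielimaea chinensis	ADB3478:16;AEJ5565:2;ADE2233:4	1.51	3.63	Elimaea nanpingensis	14.64
Tettigoniidae	Hexacentrus japonicus	ACD8277:4;ADM2486:4	1.53	2.66	Hexacentrus unicolor	12.42
Tettigoniidae	Hexacentrus unicolor	ACD7247:36	0.65	2.03	Hexacentrus japonicus	12.42
Tettigoniidae	Holochlora japonica	ADE1373:6	0.16	0.31	Holochlora venusta	9.45
Tettigoniidae	Holochlora venusta	ADB6143:12	0.05	0.31	Holochlora japonica	9.45
Tettigoniidae	Isopsera denticulata	AEJ6400:1;ADE1596:5;ADB3788:7;ACD5193:9	5.96	9.72	Deflorita deflorita	17.88
Tettigoniidae	Isopsera furcocerca	ADB4481:5	0	0	Paraxantia huangshanensis	17.96
Tettigoniidae	Isopsera sulcate	ACD7803:4	0.18	0.31	Isopsera furcocerca	19.17
Tettigoniidae	Kuwayamaea brachyptera	AEJ7401:1;AEK2062:1;AEK1896:3	1.81	2.82	Ducetia japonica	14.3
Tettigoniidae	Mecopoda niponensis	AAF0977:1;ACD8152:18	1.09	7.53	Diestramima austrosinensis	15.02
Tettigoniidae	Mirollia bispina	ADB4146:3	0.61	0.77	Mirollia bispinosa	4.61
Tettigoniidae	Mirollia bispinosa	ADB4148:3	0.1	0.15	Mirollia bispina	4.61
Tettigoniidae	Nigrimacula paraquadrinotata	ACD6675:1	N/A	N/A	Grigoriora cheni	15.82
Tettigoniidae	Palaeoagraecia ascenda	ACD8365:4	0	0	Mecopoda niponensis	16.8
Tettigoniidae	Paraxantia huangshanensis	ADB6578:1	N/A	N/A	Nigrimacula paraquadrinotata	16.76
Tettigoniidae	Phaneroptera falcata	AAL2811:2	0.31	0.31	Kuwayamaea brachyptera	15.98
Tettigoniidae	Phaneroptera nigroantennata	ACD4406:2	0.77	0.77	Ducetia japonica	14.49
Tettigoniidae	Phyllomimus klapperichi	ADM7559:1;ADB9999:4;ADB4775:6	10.3	17.47	Ducetia japonica	18.08
Tettigoniidae	Pseudocosmetura fengyangshanensis	ADW0286:1	N/A	N/A	Sinocyrtaspis brachycerca	11.19
Tettigoniidae	Pseudokuzicus pieli	ACD4648:1	N/A	N/A	Teratura megafurcula	13.71
Tettigoniidae	Pseudorhynchus concisus	ADB6233:7	0.37	1.08	Pyrgocorypha parva	16.24
Tettigoniidae	Pyrgocorypha parva	ADC0410:3	0.51	0.77	Pseudorhynchus concisus	16.24
Tettigoniidae	Qinlingea brachystylata	ADB4056:1	N/A	N/A	Ruidocollaris truncatolobata	18.9
Tettigoniidae	Ruidocollaris truncatolobata	ACD6433:15;ADB6075:5	2.2	5.85	Ducetia japonica	16.25
Tettigoniidae	Ruspolia dubia	ACD5503:1;ADE5391:3	1.09	1.55	Euconocephalus nasutus	14.22
Tettigoniidae	Ruspolia lineosa	ACD5257:26	0.79	2.03	Ruspolia dubia	15.55
Tettigoniidae	Sinochlora longifissa	AEJ1447:1;ADB3789:34	1.1	3.81	Sinochlora szechwanensis	5.68
Tettigoniidae	Sinochlora sinensis	ACD4415:1	N/A	N/A	Sinochlora szechwanensis	5.93
Tettigoniidae	Sinochlora szechwanensis	ACI0121:2;ADB3463:4	4.61	8.71	Sinochlora longifissa	5.68
Tettigoniidae	Sinocyrtaspis brachycerca	ADX3437:4	0.41	0.61	Pseudocosmetura fengyangshanensis	11.19
Tettigoniidae	Tegra novaehollandiae	ADB5353:10	0.39	1.08	Ducetia japonica	17.85
Tettigoniidae	Teratura megafurcula	ACD5306:1	N/A	N/A	Pseudokuzicus pieli	13.71
Tettigoniidae	Tettigonia chinensis	ACD6622:8	0.32	0.77	Hemielimaea chinensis	16.74
Tettigoniidae	Xiphidiopsis gurneyi	ADE1670:2	0	0	Grigoriora cheni	16.27
Tettigoniidae	Xizicus biprocerus	ADE1374:1	N/A	N/A	Pseudokuzicus pieli	14.68
Tettigoniidae	Xizicus concavilaminus	ADB3332:3	0.31	0.46	Xizicus laminatus	3.63
Tettigoniidae	Xizicus howardi	AEJ3139:1;ADB5688:10;ACD5539:3;ADE3141:4	6.13	21.64	Xizicus laminatus	3.31
Tettigoniidae	Xizicus laminatus	ADB5868:1	N/A	N/A	Xizicus howardi	3.31
Tettigoniidae	Xizicus szechwanensis	ADE0823:2;ADB3348:9	1.55	4.8	Xizicus howardi	15.37
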