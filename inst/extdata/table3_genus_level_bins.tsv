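family	taxon	bins
Tettigoniidae	Atlanticus	ADB5602:1;ADB6974:1;ADR7192:1;ADE2402:1;ADB3445:2;ADE1821:2;ADB3462:3
Tettigoniidae	Bulbistridulous	ADB3431:1
Tettigoniidae	Conanalus	ADB5687:1
Tettigoniidae	Elimaea	ADE1399:1;ADM8940:1;ADB3477:1
Tettigoniidae	Hexacentrus	ADB5446:2
Tettigoniidae	Kuwayamaea	ADB4962:1;ADE2183:1;ADE1620:13;ADB6899:27;ADB4961:4;ADB5240:4;ADB4960:6
Gryllacrididae	Phryganogryllacris	ADF3837:4
Tettigoniidae	Prohimerta	ADB4147:1
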