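species	lineage
Crassostrea gigas	Crassostrea gigas;Ostreida;Bivalvia;Mollusca;Trochozoa;Lophotrochozoa;Protostomia;Bilateria
Pinctada fucata	Pinctada fucata;Pterioida;Bivalvia;Mollusca;Trochozoa;Lophotrochozoa;Protostomia;Bilateria
Lottia gigantea	Lottia gigantea;Gastropoda;Mollusca;Trochozoa;Lophotrochozoa;Protostomia;Bilateria
Capitella teleta	Capitella teleta;Polychaeta;Annelida;Trochozoa;Lophotrochozoa;Protostomia;Bilateria
Helobdella robusta	Helobdella robusta;Clitellata;Annelida;Trochozoa;Lophotrochozoa;Protostomia;Bilateria
Schistosoma mansoni	Schistosoma mansoni;Trematoda;Neodermata;Platyhelminthes;Lophotrochozoa;Protostomia;Bilateria
Echinococcus granulosus	Echinococcus granulosus;Cestoda;Neodermata;Platyhelminthes;Lophotrochozoa;Protostomia;Bilateria
Adineta vaga	Adineta vaga;Bdelloidea;Rotifera;Lophotrochozoa;Protostomia;Bilateria
Tribolium castaneum	Tribolium castaneum;Insecta;Arthropoda;Ecdysozoa;Protostomia;Bilateria
Branchiostoma floridae	Branchiostoma floridae;Cephalochordata;Chordata;Deuterostomia;Bilateria
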