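suborder,family,subfamily,genus,species
Ensifera,Tettigoniidae,Meconematinae,Meconema,Meconema thalassinum
Ensifera,Tettigoniidae,Tettigoniinae,Tettigonia,Tettigonia viridissima
Ensifera,Tettigoniidae,Tettigoniinae,Pholidoptera,Pholidoptera griseoaptera
Ensifera,Tettigoniidae,Tettigoniinae,Platycleis,Platycleis albopunctata
Ensifera,Tettigoniidae,Tettigoniinae,Metrioptera,Metrioptera brachyptera
Ensifera,Tettigoniidae,Tettigoniinae,Metrioptera,Metrioptera roeselii
Ensifera,Tettigoniidae,Conocephalinae,Conocephalus,Conocephalus discolor
Ensifera,Tettigoniidae,Conocephalinae,Conocephalus,Conocephalus dorsalis
Ensifera,Tettigoniidae,Phaneropterinae,Leptophyes,Leptophyes punctatissima
Ensifera,Gryllidae,Nemobiinae,Nemobius,Nemobius sylvestris
Caelifera,Tetrigidae,Tetriginae,Tetrix,Tetrix ceperoi
Caelifera,Tetrigidae,Tetriginae,Tetrix,Tetrix subulata
Caelifera,Tetrigidae,Tetriginae,Tetrix,Tetrix undulata
Caelifera,Acrididae,Oedipodinae,Stethophyma,Stethophyma grossum
Caelifera,Acrididae,Gomphocerinae,Stenobothrus,Stenobothrus lineatus
Caelifera,Acrididae,Gomphocerinae,Omocestus,Omocestus rufipes
Caelifera,Acrididae,Gomphocerinae,Omocestus,Omocestus viridulus
Caelifera,Acrididae,Gomphocerinae,Chorthippus,Chorthippus brunneus
Caelifera,Acrididae,Gomphocerinae,Chorthippus,Chorthippus vagans
Caelifera,Acrididae,Gomphocerinae,Chorthippus,Chorthippus parallelus
Caelifera,Acrididae,Gomphocerinae,Chorthippus,Chorthippus albomarginatus
Caelifera,Acrididae,Gomphocerinae,Gomphocerippus,Gomphocerippus rufus
Caelifera,Acrididae,Gomphocerinae,Myrmeleotettix,Myrmeleotettix maculatus
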