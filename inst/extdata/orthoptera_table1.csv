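species,habitat_breadth,vegetation_structure,oviposition_site,diet,body_size,generations_per_year,winter_stage,phenology,wing_morph,wing_load,average_latitude,x1,x2
Meconema thalassinum,4,Tall,Vegetation,NotHerbivorous,15,HalfOrOne,Egg,7.75,Long,0.043,51.7,315,294
Tettigonia viridissima,3,Medium,Ground,NotHerbivorous,32.5,Half,Egg,7.5,Long,0.043,51.01,139,125
Pholidoptera griseoaptera,5,Tall,Vegetation,NotHerbivorous,17.5,HalfOrOne,Egg,7.5,Short,0.001,51.45,405,401
Platycleis albopunctata,2,Medium,GroundOrVegetation,NotHerbivorous,20,One,Egg,7.25,Long,0.038,50.67,52,49
Metrioptera brachyptera,1,Medium,Vegetation,NotHerbivorous,15,Half,Egg,7.5,Dimorphic,0.107,51.69,74,68
Metrioptera roeselii,6,Medium,Vegetation,NotHerbivorous,16.5,HalfOrOne,Egg,6.75,Dimorphic,0.118,51.65,71,332
Conocephalus discolor,10,Medium,Vegetation,NotHerbivorous,19,One,Egg,7.75,Dimorphic,0.042,50.82,46,378
Conocephalus dorsalis,6,Medium,Vegetation,NotHerbivorous,14.5,One,Egg,7.75,Dimorphic,0.089,51.5,137,213
Leptophyes punctatissima,4,Tall,Vegetation,Herbivorous,13.5,HalfOrOne,Egg,7.75,Short,0.001,51.41,337,424
Nemobius sylvestris,2,Tall,Ground,NotHerbivorous,8.5,Half,NotEgg,6,Short,0.015,50.82,18,19
Tetrix ceperoi,5,Short,GroundOrVegetation,Herbivorous,9,One,NotEgg,5,Long,0.13,50.84,25,27
Tetrix subulata,7,Short,GroundOrVegetation,Herbivorous,10,One,NotEgg,4.25,Dimorphic,0.127,51.54,171,282
Tetrix undulata,9,Short,GroundOrVegetation,Herbivorous,9,One,NotEgg,3.75,Dimorphic,0.137,51.78,309,298
Stethophyma grossum,2,Medium,GroundOrVegetation,Herbivorous,27,One,Egg,7.75,Long,0.022,50.89,14,7
Stenobothrus lineatus,4,Short,GroundOrVegetation,Herbivorous,20.5,One,Egg,6.25,Long,0.02,51.3,68,72
Omocestus rufipes,1,Medium,Ground,Herbivorous,16.5,One,Egg,6,Long,0.035,50.97,49,37
Omocestus viridulus,8,Medium,GroundOrVegetation,Herbivorous,18.5,One,Egg,5.75,Long,0.027,52.25,402,350
Chorthippus brunneus,7,Short,Ground,Herbivorous,19,One,Egg,5.75,Long,0.033,51.9,553,500
Chorthippus vagans,3,Medium,Ground,Herbivorous,17,One,Egg,7.25,Long,0.027,50.75,6,6
Chorthippus parallelus,14,Medium,Ground,Herbivorous,18,One,Egg,6,Dimorphic,0.034,51.73,526,503
Chorthippus albomarginatus,6,Medium,GroundOrVegetation,Herbivorous,18,One,Egg,7,Long,0.025,51.7,123,241
Gomphocerippus rufus,5,Medium,Ground,Herbivorous,19,One,Egg,7.75,Long,0.023,51.23,27,25
Myrmeleotettix maculatus,7,Short,Ground,Herbivorous,14,One,Egg,5.75,Long,0.04,52.15,206,157
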