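area,species,guild,mass_class
RYER,Herpestes urva,carnivore,medium
RYER,Pardofelis marmorata,carnivore,medium
RYER,Prionailurus bengalensis,carnivore,medium
RYER,Prionodon pardicolor,carnivore,medium
RYER,Viverra zibetha,carnivore,medium
RYER,Canis aureus,carnivore,medium-large
RYER,Catopuma temminckii,carnivore,medium-large
RYER,Cuon alpinus,carnivore,medium-large
RYER,Neofelis nebulosa,carnivore,medium-large
RYER,Atherurus macrourus,herbivore,medium
RYER,Hystrix brachyura,herbivore,medium
RYER,Macaca leonina,herbivore,medium
RYER,Trachypithecus phayrei,herbivore,medium
RYER,Muntiacus vaginalis,herbivore,medium-large
RYER,Bos gaurus,herbivore,large
RYER,Capricornis rubidus,herbivore,large
RYER,Elephas maximus,herbivore,large
RYER,Rusa unicolor,herbivore,large
RYER,Arctictis binturong,omnivore,medium
RYER,Paradoxurus hermaphroditus,omnivore,medium
RYER,Viverricula indica,omnivore,medium
RYER,Sus scrofa,omnivore,medium-large
RYER,Helarctos malayanus,omnivore,medium-large
RYER,Ursus thibetanus,omnivore,large
RYER,Manis javanica,insectivore,medium
HWS,Herpestes urva,carnivore,medium
HWS,Martes flavigula,carnivore,medium
HWS,Mustela strigidorsa,carnivore,medium
HWS,Pardofelis marmorata,carnivore,medium
HWS,Prionailurus bengalensis,carnivore,medium
HWS,Prionodon pardicolor,carnivore,medium
HWS,Viverra zibetha,carnivore,medium
HWS,Catopuma temminckii,carnivore,medium-large
HWS,Cuon alpinus,carnivore,medium-large
HWS,Neofelis nebulosa,carnivore,medium-large
HWS,Panthera tigris,carnivore,large
HWS,Atherurus macrourus,herbivore,medium
HWS,Hystrix brachyura,herbivore,medium
HWS,Macaca leonina,herbivore,medium
HWS,Macaca arctoides,herbivore,medium
HWS,Macaca mulatta,herbivore,medium
HWS,Trachypithecus shortridgei,herbivore,medium
HWS,Muntiacus vaginalis,herbivore,medium-large
HWS,Bos gaurus,herbivore,large
HWS,Capricornis rubidus,herbivore,large
HWS,Capricornis milneedwardsii,herbivore,large
HWS,Elephas maximus,herbivore,large
HWS,Rusa unicolor,herbivore,large
HWS,Arctictis binturong,omnivore,medium
HWS,Melogale personata,omnivore,medium
HWS,Paradoxurus hermaphroditus,omnivore,medium
HWS,Sus scrofa,omnivore,medium-large
HWS,Helarctos malayanus,omnivore,medium-large
HWS,Ursus thibetanus,omnivore,large
HWS,Arctonyx collaris,insectivore,medium
HWS,Manis pentadactyla,insectivore,medium
HWS,Manis javanica,insectivore,medium
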