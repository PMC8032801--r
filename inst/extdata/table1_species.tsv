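# Species metadata for the packaged repertoire matrix. `percomorphaceae`
# marks membership in Percomorphaceae (the clade over which taar13 losses
# are counted); note Atlantic cod (Gm) is a gadiform, outside that clade.
species	scientific_name	vernacular_name	group	percomorphaceae
Cm	Callorhinchus milii	Elephant shark	Cartilaginous fish	FALSE
Le	Leucoraja erinacea	Little skate	Cartilaginous fish	FALSE
Lec	Lethenteron camtschaticum	Arctic lamprey	Jawless fish	FALSE
Pm	Petromyzon marinus	Sea lamprey	Jawless fish	FALSE
Rt	Rhincodon typus	Whale shark	Cartilaginous fish	FALSE
Lo	Lepisosteus oculatus	Spotted gar	Early-derived ray-finned fish	FALSE
Aa	Anguilla anguilla	European eel	Earlier-derived teleosts	FALSE
Aj	Anguilla japonica	Japanese eel	Earlier-derived teleosts	FALSE
Am	Astyanax mexicanus	Mexican cave-fish	Earlier-derived teleosts	FALSE
Ar	Anguilla rostrata	American eel	Earlier-derived teleosts	FALSE
Cc	Cyprinus carpio	Common carp	Earlier-derived teleosts	FALSE
Ch	Clupea harengus	Herring	Earlier-derived teleosts	FALSE
Dr	Danio rerio	Zebrafish	Earlier-derived teleosts	FALSE
El	Esox lucius	Northern pike	Earlier-derived teleosts	FALSE
Ip	Ictalurus punctatus	Channel catfish	Earlier-derived teleosts	FALSE
Lw	Leuciscus waleckii	Amur ide	Earlier-derived teleosts	FALSE
Pp	Pimephales promelas	Fathead minnow	Earlier-derived teleosts	FALSE
Pyn	Pygocentrus nattereri	Red-bellied piranha	Earlier-derived teleosts	FALSE
Sa	Sinocyclocheilus anshuiensis	Anshui golden-line barbel	Earlier-derived teleosts	FALSE
Sf	Scleropages formosus	Asian bonytongue	Earlier-derived teleosts	FALSE
Sg	Sinocyclocheilus grahami	Golden-line barbel	Earlier-derived teleosts	FALSE
Sr	Sinocyclocheilus rhinocerous	Horned golden-line barbel	Earlier-derived teleosts	FALSE
Ss	Salmo salar	Atlantic salmon	Earlier-derived teleosts	FALSE
Af	Anoplopoma fimbria	Sablefish	Neoteleosts (non-Ovalentaria)	TRUE
Bp	Boleophthalmus pectinirostris	Giant blue-spotted mudskipper	Neoteleosts (non-Ovalentaria)	TRUE
Cr	Cottus rhenanus	Rhine sculpin	Neoteleosts (non-Ovalentaria)	TRUE
Cs	Cynoglossus semilaevis	Tongue sole	Neoteleosts (non-Ovalentaria)	TRUE
Dl	Dicentrarchus labrax	European seabass	Neoteleosts (non-Ovalentaria)	TRUE
Ga	Gasterosteus aculeatus	Three-spined stickleback	Neoteleosts (non-Ovalentaria)	TRUE
Gm	Gadus morhua	Atlantic cod	Neoteleosts (non-Ovalentaria)	FALSE
Hc	Hippocampus comes	Tiger tail seahorse	Neoteleosts (non-Ovalentaria)	TRUE
Lac	Lates calcarifer	Asian sea bass	Neoteleosts (non-Ovalentaria)	TRUE
Lb	Labrus bergylta	Ballan wrasse	Neoteleosts (non-Ovalentaria)	TRUE
Lc	Larimichthys crocea	Yellow croaker	Neoteleosts (non-Ovalentaria)	TRUE
Mim	Miichthys miiuy	Mi-iuy croaker	Neoteleosts (non-Ovalentaria)	TRUE
Moa	Monopterus albus	Asian swamp eel	Neoteleosts (non-Ovalentaria)	TRUE
Mom	Mola mola	Ocean sunfish	Neoteleosts (non-Ovalentaria)	TRUE
Ms	Morone saxatilis	Striped bass	Neoteleosts (non-Ovalentaria)	TRUE
Nc	Notothenia coriiceps	Black rockcod	Neoteleosts (non-Ovalentaria)	TRUE
Pa	Pampus argenteus	Silver pomfret	Neoteleosts (non-Ovalentaria)	TRUE
Pem	Periophthalmus magnuspinnatus	Giant-fin mudskipper	Neoteleosts (non-Ovalentaria)	TRUE
Po	Paralichthys olivaceus	Bastard halibut	Neoteleosts (non-Ovalentaria)	TRUE
Ps	Periophthalmodon schlosseri	Giant mudskipper	Neoteleosts (non-Ovalentaria)	TRUE
Py	Pseudopleuronectes yokohamae	Marbled flounder	Neoteleosts (non-Ovalentaria)	TRUE
Sea	Sebastes aleutianus	Rougheye rockfish	Neoteleosts (non-Ovalentaria)	TRUE
Sem	Sebastes minor	Akagaya rockfish	Neoteleosts (non-Ovalentaria)	TRUE
Ser	Sebastes rubrivinctus	Flag rockfish	Neoteleosts (non-Ovalentaria)	TRUE
Ses	Sebastes steindachneri	Yanaginomai rockfish	Neoteleosts (non-Ovalentaria)	TRUE
Sh	Scartelaos histophorus	Blue mudskipper	Neoteleosts (non-Ovalentaria)	TRUE
Sn	Sebastes nigrocinctus	Tiger rockfish	Neoteleosts (non-Ovalentaria)	TRUE
Tf	Takifugu flavidus	Yellowbelly pufferfish	Neoteleosts (non-Ovalentaria)	TRUE
Tn	Tetraodon nigroviridis	Spotted green pufferfish	Neoteleosts (non-Ovalentaria)	TRUE
To	Thunnus orientalis	Pacific bluefin tuna	Neoteleosts (non-Ovalentaria)	TRUE
Tr	Takifugu rubripes	Japanese pufferfish	Neoteleosts (non-Ovalentaria)	TRUE
Ac	Amphilophus citrinellus	Midas cichlid	Ovalentaria	TRUE
Al	Austrofundulus limnaeus	Annual killifish	Ovalentaria	TRUE
Cn	Cyprinodon nevadensis	Amargosa pupfish	Ovalentaria	TRUE
Cv	Cyprinodon variegatus	Sheepshead pupfish	Ovalentaria	TRUE
Fh	Fundulus heteroclitus	Mummichog	Ovalentaria	TRUE
Hb	Haplochromis burtoni	Burton's mouthbrooder	Ovalentaria	TRUE
Km	Kryptolebias marmoratus	Mangrove killifish	Ovalentaria	TRUE
Mc	Mchenga conophoros	Happy cichlid	Ovalentaria	TRUE
Mz	Maylandia zebra	Zebra mbuna	Ovalentaria	TRUE
Nb	Neolamprologus brichardi	Lyretail cichlid	Ovalentaria	TRUE
Nf	Nothobranchius furzeri	Turquoise killifish	Ovalentaria	TRUE
Ol	Oryzias latipes	Medaka	Ovalentaria	TRUE
On	Oreochromis niloticus	Nile tilapia	Ovalentaria	TRUE
Pf	Poecilia formosa	Amazon molly	Ovalentaria	TRUE
Pl	Poecilia latipinna	Sailfin molly	Ovalentaria	TRUE
Pom	Poecilia mexicana	Shortfin molly	Ovalentaria	TRUE
Pr	Poecilia reticulata	Guppy	Ovalentaria	TRUE
Pun	Pundamilia nyererei	Nyerere's cichlid	Ovalentaria	TRUE
Stp	Stegastes partitus	Bicolor damselfish	Ovalentaria	TRUE
Xc	Xiphophorus couchianus	Monterrey platyfish	Ovalentaria	TRUE
Xh	Xiphophorus hellerii	Green swordtail	Ovalentaria	TRUE
Xm	Xiphophorus maculatus	Southern platyfish	Ovalentaria	TRUE
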