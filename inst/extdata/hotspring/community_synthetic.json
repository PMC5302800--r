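{"format":"mofba-community","version":1,"strains":{"SYN":{"id":"SYN","mets":{"id":["ph","chx","nh3i","hv","h2o","co2","no3","nh3","ac","glyc"],"external":[false,false,false,true,true,true,true,true,true,true],"name":["ph","chx","nh3i","hv","h2o","co2","no3","nh3","ac","glyc"],"compartment":["SYN","SYN","SYN","SYN","SYN","SYN","SYN","SYN","SYN","SYN"],"mu0":[null,null,null,null,null,null,null,null,null,null],"conc_lo":[null,null,null,null,null,null,null,null,null,null],"conc_hi":[null,null,null,null,null,null,null,null,null,null]},"rxns":{"id":["PSII","RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN","RXN-961","NAR","AMT","ACS","BIO_SYN","EX_hv","EX_h2o","EX_co2","EX_no3","EX_nh3","EX_ac","EX_glyc"],"lb":[0,0,0,0,-1000,0,0,-1,-1000,-2,-10,-10,0,0],"ub":[1000,1000,1000,1000,1000,1000,1000,0,1000,1000,1000,1000,1000,1000],"kind":["internal","internal","internal","internal","internal","internal","biomass","exchange","exchange","exchange","exchange","exchange","exchange","exchange"]},"stoich":{"met":["ph","hv","h2o","chx","co2","chx","glyc","nh3i","no3","nh3i","nh3","ph","chx","ac","ph","chx","nh3i","hv","h2o","co2","no3","nh3","ac","glyc"],"rxn":["PSII","PSII","PSII","RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN","RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN","RXN-961","RXN-961","NAR","NAR","AMT","AMT","ACS","ACS","ACS","BIO_SYN","BIO_SYN","BIO_SYN","EX_hv","EX_h2o","EX_co2","EX_no3","EX_nh3","EX_ac","EX_glyc"],"coef":[1,-1,-1,1,-1,-1,1,1,-1,1,-1,-0.820224719101124,-1,1,-1,-0.407407407407407,-0.965242165242165,-1,-1,-1,-1,-1,-1,-1]},"objective":[0,0,0,0,0,0,1,0,0,0,0,0,0,0]},"FAP":{"id":"FAP","mets":{"id":["ph","chx","hv","co2","nh3","ac","glyc"],"external":[false,false,true,true,true,true,true],"name":["ph","chx","hv","co2","nh3","ac","glyc"],"compartment":["FAP","FAP","FAP","FAP","FAP","FAP","FAP"],"mu0":[null,null,null,null,null,null,null],"conc_lo":[null,null,null,null,null,null,null],"conc_hi":[null,null,null,null,null,null,null]},"rxns":{"id":["PSB","CFX","ACU","GLU","RSP","BIO_FAP","EX_hv","EX_co2","EX_nh3","EX_ac","EX_glyc"],"lb":[0,0,0,-1000,0,0,-1,-2,-10,-2,-10],"ub":[1000,1000,1000,1000,1000,1000,0,1000,0,0,1000],"kind":["internal","internal","internal","internal","internal","biomass","exchange","exchange","exchange","exchange","exchange"]},"stoich":{"met":["ph","hv","chx","co2","chx","ac","chx","glyc","chx","co2","ph","chx","nh3","hv","co2","nh3","ac","glyc"],"rxn":["PSB","PSB","CFX","CFX","ACU","ACU","GLU","GLU","RSP","RSP","BIO_FAP","BIO_FAP","BIO_FAP","EX_hv","EX_co2","EX_nh3","EX_ac","EX_glyc"],"coef":[1,-1,1,-1,1,-1,1,-1,-1,1,-1,-0.760869565217391,-1,-1,-1,-1,-1,-1]},"objective":[0,0,0,0,0,1,0,0,0,0,0]},"SRB":{"id":"SRB","mets":{"id":["ac","nh3","so4","h2s"],"external":[true,true,true,true],"name":["ac","nh3","so4","h2s"],"compartment":["SRB","SRB","SRB","SRB"],"mu0":[null,null,null,null],"conc_lo":[null,null,null,null],"conc_hi":[null,null,null,null]},"rxns":{"id":["BIO_SRB","EX_ac","EX_nh3","EX_so4","EX_h2s"],"lb":[0,-1,-10,-10,0],"ub":[1000,0,0,0,1000],"kind":["biomass","exchange","exchange","exchange","exchange"]},"stoich":{"met":["ac","nh3","so4","h2s","ac","nh3","so4","h2s"],"rxn":["BIO_SRB","BIO_SRB","BIO_SRB","BIO_SRB","EX_ac","EX_nh3","EX_so4","EX_h2s"],"coef":[-1,-0.830769230769231,-0.5,0.5,-1,-1,-1,-1]},"objective":[1,0,0,0,0]}},"pool":{"shared":["hv","h2o","co2","no3","nh3","ac","glyc","so4","h2s"],"envBounds":{"met":["hv","h2o","co2","no3","nh3","ac","glyc","so4","h2s"],"lb":[-1,-1000,-2,-10,-10,0,0,-10,0],"ub":[0,1000,1000,0,1000,1000,1000,1000,1000]}},"couplings":[{"terms":{"strain":["SYN","SYN"],"rxn":["RXN-961","RIBULOSE-BISPHOSPHATE-CARBOXYLASE-RXN"],"coef":[1,-0.03]},"relation":"eq","rhs":0},{"terms":{"strain":["SYN","SYN"],"rxn":["NAR","PSII"],"coef":[1,-0.5]},"relation":"eq","rhs":0},{"terms":{"strain":[".pool",".pool"],"rxn":["EX_no3","EX_nh3"],"coef":[1,1]},"relation":"ge","rhs":-1},{"terms":{"strain":[".pool",".pool",".pool"],"rxn":["EX_co2","EX_ac","EX_glyc"],"coef":[1,1,1]},"relation":"ge","rhs":-1}]}
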