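assay_id,mirna_id,sequence,annotation,analyzable
000377,hsa-let-7a-5p,UGAGGUAGUAGGUUGUAUAGUU,Inflammatory/immune response,TRUE
002619,hsa-let-7b-5p,UGAGGUAGUAGGUUGUGUGGUU,Angiogenesis/inflammatory and immune response,TRUE
000379,hsa-let-7c-5p,UGAGGUAGUAGGUUGUAUGGUU,Inflammatory/immune response,TRUE
000439,hsa-miR-103a-3p,AGCAGCAUUGUACAGGGCUAUGA,Cell migration/wound healing,TRUE
000443,hsa-miR-107,AGCAGCAUUGUACAGGGCUAUCA,Inflammatory response/cell migration/wound healing,TRUE
000449,hsa-miR-125b-5p,UCCCUGAGACCCUAACUUGUGA,Cell proliferation/neuronal integrity,TRUE
002884,hsa-miR-1274b,UCCCUGUUCGGGCGCCA,Potential normalizer (CSF),TRUE
002861,hsa-miR-1298-5p,UUCAUUCGGCUGUCCAGAUGUA,Neural regeneration,TRUE
000457,hsa-miR-132-3p,UAACAGUCUACAGCCAUGGUCG,Vascular angiogenesis,TRUE
000464,hsa-miR-142-3p,UGUAGUGUUUCCUACUUUAUGGA,Inflammatory and immune response,TRUE
002248,hsa-miR-142-5p,CAUAAAGUAGAAAGCACUACU,Inflammatory and immune response,TRUE
002676,hsa-miR-144-3p,UACAGUAUAGAUGAUGUACU,Proliferation/apoptosis/oxidative stress,TRUE
000468,hsa-miR-146a-5p,UGAGAACUGAAUUCCAUGGGUU,Inflammatory and immune response,TRUE
001097,hsa-miR-146b-5p,UGAGAACUGAAUUCCAUAGGCU,Inflammatory and immune response,TRUE
000473,hsa-miR-150-5p,UCUCCCAACCCUUGUACCAGUG,Inflammatory and immune response/BBB permeability,TRUE
001191,hsa-miR-153-3p,UUGCAUAGUCACAAAAGUGAUC,Neurogenesis,TRUE
002623,hsa-miR-155-5p,UUAAUGCUAAUCGUGAUAGGGGU,Inflammatory and immune response/arteriogenesis,TRUE
000389,hsa-miR-15a-5p,UAGCAGCACAUAAUGGUUUGUG,Vascular angiogenesis,TRUE
000390,hsa-miR-15b-5p,UAGCAGCACAUCAUGGUUUACA,Apoptosis/inflammatory response,TRUE
000391,hsa-miR-16-5p,UAGCAGCACGUAAAUAUUGGCG,Vascular angiogenesis,TRUE
002308,hsa-miR-17-5p,CAAAGUGCUUACAGUGCAGGUAG,Neovascularization/apoptosis/proliferation,TRUE
000480,hsa-miR-181a-5p,AACAUUCAACGCUGUCGGUGAGU,Apoptosis/inflammatory response,TRUE
000482,hsa-miR-181c-5p,AACAUUCAACCUGUCGGUGAGU,Apoptosis/inflammatory response,TRUE
000494,hsa-miR-195-5p,UAGCAGCACAGAAAUAUUGGC,Homeostasis of vessel smooth muscle cells,TRUE
000396,hsa-miR-19b-3p,UGUGCAAAUCCAUGCAAAACUGA,Neovascularization/apoptosis/proliferation,TRUE
000508,hsa-miR-204-5p,UUCCCUUUGUCAUCCUAUGCCU,Apoptosis/proliferation,TRUE
000580,hsa-miR-20a-5p,UAAAGUGCUUAUAGUGCAGGUAG,Neovascularization/apoptosis/proliferation,TRUE
000397,hsa-miR-21-5p,UAGCUUAUCAGACUGAUGUUGA,Apoptosis/inflammatory,TRUE
000524,hsa-miR-221-3p,AGCUACAUUGUCUGCUGGGUUUC,Apoptosis/inflammatory,TRUE
002295,hsa-miR-223-3p,UGUCAGUUUGUCAAAUACCCCA,Inflammatory and immune response,TRUE
000399,hsa-miR-23a-3p,AUCACAUUGCCAGGGAUUUCC,Mitochondrial function/apoptosis,TRUE
000400,hsa-miR-23b-3p,AUCACAUUGCCAGGGAUUACC,Mitochondrial function/apoptosis,TRUE
000402,hsa-miR-24-3p,UGGCUCAGUUCAGCAGGAACAG,Apoptosis/proliferation,TRUE
000408,hsa-miR-27a-3p,UUCACAGUGGCUAAGUUCCGC,Autophagy/apoptosis,TRUE
000409,hsa-miR-27b-3p,UUCACAGUGGCUAAGUUCUGC,Autophagy/apoptosis,TRUE
002112,hsa-miR-29a-3p,UAGCACCAUCUGAAAUCGGUUA,Apoptosis/proliferation/immune response,TRUE
000413,hsa-miR-29b-3p,UAGCACCAUUUGAAAUCAGUGUU,Apoptosis/proliferation/immune response,TRUE
000587,hsa-miR-29c-3p,UAGCACCAUUUGAAAUCGGUUA,Apoptosis/proliferation/immune response,TRUE
000426,hsa-miR-34a-5p,UGGCAGUGUCUUAGCUGGUUGU,Autophagy/inflammatory response,TRUE
002102,hsa-miR-34b-3p,CAAUCACUAACUCCACUGCCAU,Autophagy/inflammatory response,TRUE
001043,hsa-miR-497-5p,CAGCAGCACACUGUGGUUUGU,Apoptosis/inflammatory response,TRUE
002268,hsa-miR-874-3p,CUGCCCUGGCCCGAGGGACCGA,Apoptosis/inflammatory response,TRUE
000583,hsa-miR-9-5p,UCUUUGGUUAUCUAGCUGUAUGA,Neurogenesis and differentiation,TRUE
000430,hsa-miR-92a-3p,UAUUGCACUUGUCCCGGCCUG,Neovascularization/apoptosis/proliferation,TRUE
001182,hsa-miR-124-3p,UAAGGCACGCGGUGAAUGCC,"Neurogenesis, differentiation, and inflammatory response",TRUE
002571,mmu-miR-155-5p,UUAAUGCUAAUUGUGAUAGGGGU,Rodent-specific control (excluded from analysis),FALSE
001141,hsa-miR-451a,AAACCGUUACCAUUACUGAGUU,Apoptosis/inflammatory response/RBC enriched,TRUE
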