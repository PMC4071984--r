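"FluxID","Rxns","Net flux","Carbon_transitions"
"R1","Subs_PYR_EX -> PYR",0,"abc -> abc"
"R2","PYR -> ACCOA + Ind_CO2",0,"abc -> bc + a"
"R3","ACCOA + OAA -> IsoCit",0,"ab + cdef -> fedbac"
"R4","IsoCit -> AKG + Ind_CO2",0,"abcdef -> abcde + f"
"R5","AKG -> Sym_SUC + Ind_CO2",0,"abcde -> abcd + e"
"R6","Sym_SUC -> OAA",1,"abcd -> abcd"
"R7","PYR + Ind_CO2 -> OAA",2,"abc + d -> abcd"
"R8","AKG -> [AKG_B]",0,""
"R9","OAA -> [OAA_B]",0,""
"R10","OAA -> [LYS_B]",0,""
"R11","PYR -> [PYR_B]",0,""
"R12","PYR -> [LYS_B]",0,""
"R13","PYR -> [VAL_B]",0,""
"R14","Subs_GLU_EX -> AKG",0,"abcde -> abcde"
"R15","OAA -> Sym_SUC",1,"abcd -> abcd"
"R16","OAA -> PYR + Ind_CO2",2,"abcd -> abc + d"
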