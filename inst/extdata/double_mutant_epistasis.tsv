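double_id	temperature	epsilon	var_epsilon	p
rhoA43T_rpoBI572F	42.2	-0.2325	0.0182	0.0000
rhoA43T_rpoBI572L	42.2	-0.2680	0.0418	0.0043
rhoT231A_rpoBI572F	42.2	-0.2430	0.0218	0.0001
rhoT231A_rpoBI572L	42.2	-0.1802	0.0505	0.0180
rhoI15F_rpoBI572F	42.2	-0.0370	0.0215	0.4431
rhoI15F_rpoBI572L	42.2	-0.0010	0.0318	0.9866
rhoI15N_rpoBI572F	42.2	-0.0635	0.02874	0.2938
rhoI15N_rpoBI572L	42.2	-0.0446	0.0430	0.5898
rhoA43T_rpoBI572F	37.0	-0.0319	0.0033	0.116
rhoA43T_rpoBI572L	37.0	-0.0171	0.0031	0.383
rhoT231A_rpoBI572F	37.0	-0.0430	0.0034	0.036
rhoT231A_rpoBI572L	37.0	-0.0155	0.0034	0.401
rhoI15F_rpoBI572F	37.0	-0.0304	0.0045	0.146
rhoI15F_rpoBI572L	37.0	-0.0224	0.0033	0.281
rhoI15N_rpoBI572F	37.0	-0.0318	0.0027	0.073
rhoI15N_rpoBI572L	37.0	-0.0360	0.0014	0.020
rhoA43T_rpoBI572F	20.0	-0.0283	0.0020	0.0508
rhoA43T_rpoBI572L	20.0	-0.0468	0.0023	0.0188
rhoT231A_rpoBI572F	20.0	-0.0024	0.0053	0.9194
rhoT231A_rpoBI572L	20.0	0.0377	0.0045	0.0772
rhoI15F_rpoBI572F	20.0	-0.0425	0.0045	0.0509
rhoI15F_rpoBI572L	20.0	0.0078	0.0037	0.7137
rhoI15N_rpoBI572F	20.0	0.0184	0.0029	0.2600
rhoI15N_rpoBI572L	20.0	-0.0118	0.0018	0.4721
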