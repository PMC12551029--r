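cpg	coefficient
cg10636246	-0.231
cg05575921	0.184
cg17501210	-0.158
cg09349128	0.142
cg03957124	-0.205
cg19821297	0.176
cg06126421	-0.119
cg25325512	0.163
cg14975410	-0.187
cg08548559	0.151
cg21566642	-0.134
cg01940273	0.198
cg05951221	-0.172
cg23576855	0.145
cg26703534	-0.126
cg11554391	0.209
cg18146737	-0.154
cg04885881	0.137
cg12803068	-0.191
cg07123182	0.168
cg24859433	-0.122
cg02650017	0.215
cg16867657	-0.148
cg22454769	0.131
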