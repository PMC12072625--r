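name,hemisphere,group,label_id,networks
entorhinal,left,temporal,1,
parahippocampal,left,temporal,2,
fusiform,left,temporal,3,
superior_temporal,left,temporal,4,
middle_temporal,left,temporal,5,DMN
inferior_temporal,left,temporal,6,CEN_FPN
transverse_temporal,left,temporal,7,
temporal_pole,left,temporal,8,
superior_frontal,left,frontal,9,
rostral_middle_frontal,left,frontal,10,CEN_FPN
caudal_middle_frontal,left,frontal,11,
pars_opercularis,left,frontal,12,
pars_triangularis,left,frontal,13,
pars_orbitalis,left,frontal,14,
lateral_orbitofrontal,left,frontal,15,CEN_FPN
medial_orbitofrontal,left,frontal,16,DMN
precentral,left,frontal,17,
paracentral,left,frontal,18,
frontal_pole,left,frontal,19,
postcentral,left,parietal,20,
supramarginal,left,parietal,21,
superior_parietal,left,parietal,22,
inferior_parietal,left,parietal,23,CEN_FPN
precuneus,left,parietal,24,DMN
lingual,left,occipital,25,
pericalcarine,left,occipital,26,
cuneus,left,occipital,27,
lateral_occipital,left,occipital,28,
rostral_anterior_cingulate,left,cingulate,29,SN
caudal_anterior_cingulate,left,cingulate,30,CEN_FPN
posterior_cingulate,left,cingulate,31,DMN
isthmus_cingulate,left,cingulate,32,
thalamus,left,basal_ganglia,33,
caudate,left,basal_ganglia,34,CEN_FPN
putamen,left,basal_ganglia,35,
pallidum,left,basal_ganglia,36,
insula,left,insula,37,SN
angular_gyrus,left,parietal,38,DMN
entorhinal,right,temporal,101,
parahippocampal,right,temporal,102,
fusiform,right,temporal,103,
superior_temporal,right,temporal,104,
middle_temporal,right,temporal,105,DMN
inferior_temporal,right,temporal,106,CEN_FPN
transverse_temporal,right,temporal,107,
temporal_pole,right,temporal,108,
superior_frontal,right,frontal,109,
rostral_middle_frontal,right,frontal,110,CEN_FPN
caudal_middle_frontal,right,frontal,111,
pars_opercularis,right,frontal,112,
pars_triangularis,right,frontal,113,
pars_orbitalis,right,frontal,114,
lateral_orbitofrontal,right,frontal,115,CEN_FPN
medial_orbitofrontal,right,frontal,116,DMN
precentral,right,frontal,117,
paracentral,right,frontal,118,
frontal_pole,right,frontal,119,
postcentral,right,parietal,120,
supramarginal,right,parietal,121,
superior_parietal,right,parietal,122,
inferior_parietal,right,parietal,123,CEN_FPN
precuneus,right,parietal,124,DMN
lingual,right,occipital,125,
pericalcarine,right,occipital,126,
cuneus,right,occipital,127,
lateral_occipital,right,occipital,128,
rostral_anterior_cingulate,right,cingulate,129,SN
caudal_anterior_cingulate,right,cingulate,130,CEN_FPN
posterior_cingulate,right,cingulate,131,DMN
isthmus_cingulate,right,cingulate,132,
thalamus,right,basal_ganglia,133,
caudate,right,basal_ganglia,134,CEN_FPN
putamen,right,basal_ganglia,135,
pallidum,right,basal_ganglia,136,
insula,right,insula,137,SN
angular_gyrus,right,parietal,138,DMN
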