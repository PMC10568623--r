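roi,name,hemisphere,lobe
1,rh_superiorfrontal,right,frontal
2,lh_superiorfrontal,left,frontal
3,rh_rostralmiddlefrontal,right,frontal
4,lh_rostralmiddlefrontal,left,frontal
5,rh_caudalmiddlefrontal,right,frontal
6,lh_caudalmiddlefrontal,left,frontal
7,rh_parsopercularis,right,frontal
8,lh_parsopercularis,left,frontal
9,rh_parstriangularis,right,frontal
10,lh_parstriangularis,left,frontal
11,rh_parsorbitalis,right,frontal
12,lh_parsorbitalis,left,frontal
13,rh_lateralorbitofrontal,right,frontal
14,lh_lateralorbitofrontal,left,frontal
15,rh_medialorbitofrontal,right,frontal
16,lh_medialorbitofrontal,left,frontal
17,rh_precentral,right,frontal
18,lh_precentral,left,frontal
19,rh_frontalpole,right,frontal
20,lh_frontalpole,left,frontal
21,rh_superiortemporal,right,temporal
22,lh_superiortemporal,left,temporal
23,rh_middletemporal,right,temporal
24,lh_middletemporal,left,temporal
25,rh_inferiortemporal,right,temporal
26,lh_inferiortemporal,left,temporal
27,rh_bankssts,right,temporal
28,lh_bankssts,left,temporal
29,rh_fusiform,right,temporal
30,lh_fusiform,left,temporal
31,rh_transversetemporal,right,temporal
32,lh_transversetemporal,left,temporal
33,rh_entorhinal,right,temporal
34,lh_entorhinal,left,temporal
35,rh_temporalpole,right,temporal
36,lh_temporalpole,left,temporal
37,rh_parahippocampal,right,temporal
38,lh_parahippocampal,left,temporal
39,rh_postcentral,right,parietal
40,lh_postcentral,left,parietal
41,rh_supramarginal,right,parietal
42,lh_supramarginal,left,parietal
43,rh_superiorparietal,right,parietal
44,lh_superiorparietal,left,parietal
45,rh_inferiorparietal,right,parietal
46,lh_inferiorparietal,left,parietal
47,rh_precuneus,right,parietal
48,lh_precuneus,left,parietal
49,rh_lateraloccipital,right,occipital
50,lh_lateraloccipital,left,occipital
51,rh_lingual,right,occipital
52,lh_lingual,left,occipital
53,rh_cuneus,right,occipital
54,lh_cuneus,left,occipital
55,rh_pericalcarine,right,occipital
56,lh_pericalcarine,left,occipital
57,rh_isthmuscingulate,right,isthmus
58,lh_isthmuscingulate,left,isthmus
59,rh_paracentral,right,other
60,lh_paracentral,left,other
61,rh_caudalanteriorcingulate,right,other
62,lh_caudalanteriorcingulate,left,other
63,rh_rostralanteriorcingulate,right,other
64,lh_rostralanteriorcingulate,left,other
65,rh_posteriorcingulate,right,other
66,lh_posteriorcingulate,left,other
67,rh_insula,right,other
68,lh_insula,left,other
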