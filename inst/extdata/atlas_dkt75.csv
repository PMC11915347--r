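"roi_id","name","hemisphere","lobe","is_cortical","homotopic_partner","system_tags"
1,"caudalanteriorcingulate-L","L","cingulate",TRUE,32,""
2,"caudalmiddlefrontal-L","L","frontal",TRUE,33,""
3,"cuneus-L","L","occipital",TRUE,34,"VIS"
4,"entorhinal-L","L","temporal",TRUE,35,""
5,"fusiform-L","L","temporal",TRUE,36,""
6,"inferiorparietal-L","L","parietal",TRUE,37,""
7,"inferiortemporal-L","L","temporal",TRUE,38,""
8,"isthmuscingulate-L","L","cingulate",TRUE,39,""
9,"lateraloccipital-L","L","occipital",TRUE,40,"VIS"
10,"lateralorbitofrontal-L","L","frontal",TRUE,41,""
11,"lingual-L","L","occipital",TRUE,42,""
12,"medialorbitofrontal-L","L","frontal",TRUE,43,""
13,"middletemporal-L","L","temporal",TRUE,44,""
14,"parahippocampal-L","L","temporal",TRUE,45,""
15,"paracentral-L","L","frontal",TRUE,46,"SM"
16,"parsopercularis-L","L","frontal",TRUE,47,""
17,"parsorbitalis-L","L","frontal",TRUE,48,""
18,"parstriangularis-L","L","frontal",TRUE,49,""
19,"pericalcarine-L","L","occipital",TRUE,50,"VIS"
20,"postcentral-L","L","parietal",TRUE,51,"SM"
21,"posteriorcingulate-L","L","cingulate",TRUE,52,""
22,"precentral-L","L","frontal",TRUE,53,"SM"
23,"precuneus-L","L","parietal",TRUE,54,""
24,"rostralanteriorcingulate-L","L","cingulate",TRUE,55,""
25,"rostralmiddlefrontal-L","L","frontal",TRUE,56,""
26,"superiorfrontal-L","L","frontal",TRUE,57,""
27,"superiorparietal-L","L","parietal",TRUE,58,""
28,"superiortemporal-L","L","temporal",TRUE,59,""
29,"supramarginal-L","L","parietal",TRUE,60,""
30,"transversetemporal-L","L","temporal",TRUE,61,""
31,"insula-L","L","insular",TRUE,62,""
32,"caudalanteriorcingulate-R","R","cingulate",TRUE,1,""
33,"caudalmiddlefrontal-R","R","frontal",TRUE,2,""
34,"cuneus-R","R","occipital",TRUE,3,"VIS"
35,"entorhinal-R","R","temporal",TRUE,4,""
36,"fusiform-R","R","temporal",TRUE,5,""
37,"inferiorparietal-R","R","parietal",TRUE,6,""
38,"inferiortemporal-R","R","temporal",TRUE,7,""
39,"isthmuscingulate-R","R","cingulate",TRUE,8,""
40,"lateraloccipital-R","R","occipital",TRUE,9,"VIS"
41,"lateralorbitofrontal-R","R","frontal",TRUE,10,""
42,"lingual-R","R","occipital",TRUE,11,""
43,"medialorbitofrontal-R","R","frontal",TRUE,12,""
44,"middletemporal-R","R","temporal",TRUE,13,""
45,"parahippocampal-R","R","temporal",TRUE,14,""
46,"paracentral-R","R","frontal",TRUE,15,"SM"
47,"parsopercularis-R","R","frontal",TRUE,16,""
48,"parsorbitalis-R","R","frontal",TRUE,17,""
49,"parstriangularis-R","R","frontal",TRUE,18,""
50,"pericalcarine-R","R","occipital",TRUE,19,"VIS"
51,"postcentral-R","R","parietal",TRUE,20,"SM"
52,"posteriorcingulate-R","R","cingulate",TRUE,21,""
53,"precentral-R","R","frontal",TRUE,22,"SM"
54,"precuneus-R","R","parietal",TRUE,23,""
55,"rostralanteriorcingulate-R","R","cingulate",TRUE,24,""
56,"rostralmiddlefrontal-R","R","frontal",TRUE,25,""
57,"superiorfrontal-R","R","frontal",TRUE,26,""
58,"superiorparietal-R","R","parietal",TRUE,27,""
59,"superiortemporal-R","R","temporal",TRUE,28,""
60,"supramarginal-R","R","parietal",TRUE,29,""
61,"transversetemporal-R","R","temporal",TRUE,30,""
62,"insula-R","R","insular",TRUE,31,""
63,"brainstem","medial","subcortical",FALSE,,""
64,"thalamus-L","L","subcortical",FALSE,65,"thalamus"
65,"thalamus-R","R","subcortical",FALSE,64,"thalamus"
66,"caudate-L","L","subcortical",FALSE,67,""
67,"caudate-R","R","subcortical",FALSE,66,""
68,"lenticular-L","L","subcortical",FALSE,69,""
69,"lenticular-R","R","subcortical",FALSE,68,""
70,"amygdala-L","L","subcortical",FALSE,71,""
71,"amygdala-R","R","subcortical",FALSE,70,""
72,"hippocampus-L","L","subcortical",FALSE,73,""
73,"hippocampus-R","R","subcortical",FALSE,72,""
74,"cerebellum-L","L","subcortical",FALSE,75,""
75,"cerebellum-R","R","subcortical",FALSE,74,""
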