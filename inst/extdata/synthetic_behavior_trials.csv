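animal,condition,treatment,trial,t_novel_s,t_familiar_s
rat1,Overlapping,VEH,1,11.2,10.8
rat1,Overlapping,VEH,2,12.5,11.9
rat1,Overlapping,VEH,3,10.1,10.4
rat1,Overlapping,VEH,4,13.0,11.1
rat1,Overlapping,VEH,5,12.2,10.3
rat1,Overlapping,VEH,TEST,21.0,9.0
rat1,Stable,CBD,1,9.8,10.1
rat1,Stable,CBD,2,11.4,11.0
rat1,Stable,CBD,3,10.9,10.6
rat1,Stable,CBD,4,12.1,11.8
rat1,Stable,CBD,5,11.7,11.2
rat1,Stable,CBD,TEST,18.4,11.6
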