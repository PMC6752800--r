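sign	r2_model1	r2_model2
arachnodactyly	20.1	25.5
aortic_dissection	0	13.4
aortic_ectasia	8.8	21.2
ectopia_lentis	9.2	15.6
flatfoot	11.3	21.4
hyperlaxity	0	18.3
mitral_valve_prolapse	5.2	14.8
myopia	0	15.8
pectus_carinatum	3.6	16.6
reduced_elbow_extension	0	15.7
stretch_marks	0	12.2
scoliosis	5.9	14.5
thumb_sign	17.6	21.9
wrist_sign	8	17.8
ghent_positivity	24.8	26.6
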