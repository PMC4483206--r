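# Default physiology for a ~20 g laboratory mouse.
# Reconstruction compiled from standard reference compilations; user-replaceable.
name,value,units,gsd
body_mass,20,g,1.1
blood_volume,1.44,mL,1.2
cardiac_output,840,mL/h,1.2
lung.blood_flow,17,mL/h,1.2
liver.blood_flow,135,mL/h,1.2
spleen.blood_flow,9,mL/h,1.2
kidneys.blood_flow,110,mL/h,1.2
heart.blood_flow,55,mL/h,1.2
brain.blood_flow,22,mL/h,1.2
GIT_tissue.blood_flow,120,mL/h,1.2
remainder.blood_flow,350,mL/h,1.2
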