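# Default physiology for a ~250 g laboratory rat.
# Reconstruction compiled from standard reference compilations (Brown et al.
# 1997-style tables); user-replaceable. gsd = geometric standard deviation
# used by the Monte Carlo uncertainty module.
name,value,units,gsd
body_mass,250,g,1.1
blood_volume,16,mL,1.2
cardiac_output,4920,mL/h,1.2
lung.blood_flow,100,mL/h,1.2
liver.blood_flow,900,mL/h,1.2
spleen.blood_flow,50,mL/h,1.2
kidneys.blood_flow,700,mL/h,1.2
heart.blood_flow,240,mL/h,1.2
brain.blood_flow,100,mL/h,1.2
GIT_tissue.blood_flow,750,mL/h,1.2
remainder.blood_flow,2000,mL/h,1.2
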