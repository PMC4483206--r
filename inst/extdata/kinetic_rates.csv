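# Default first-order kinetic rate constants for the nanoparticle PBPK model.
# These values are reconstructions chosen on domain grounds (the original
# parameterization is not publicly deposited); they are data, not code, and
# user-replaceable. x_* are dimensionless capillary-permeability multipliers
# applied to organ blood flow / blood volume. k_ab (lung deposition -> blood)
# defaults to 0 because it is the quantity fitted to translocation data.
# k_filt_enhanced is the blood -> urine rate switched on for particles below
# the renal filtration threshold (and ionic controls).
name,value,units,gsd
x_continuous,0.001,-,1.5
x_fenestrated,0.01,-,1.5
x_sinusoidal,0.1,-,1.5
k_release,0.01,1/h,1.5
k_ab,0,1/h,1.5
k_mc,0.02,1/h,1.5
k_bile,0.05,1/h,1.5
k_urine,0.02,1/h,1.5
k_filt,0,1/h,1.5
k_filt_enhanced,0.1,1/h,1.5
k_git,0.05,1/h,1.5
k_abs_git,0,1/h,1.5
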