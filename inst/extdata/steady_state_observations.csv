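condition,pathway,isotope,formaldehyde_uM,formaldehyde_sd_uM,nad_ratio,nad_ratio_sd,n_replicates
none,mdh_only,H,56,4,31.3,NA,3
none,full_pathway,H,46.6667,5.1,31.3,NA,3
none,full_pathway,D,31.1111,6.2,31.3,NA,3
xylose,mdh_only,H,35.25,3.5,31.3,NA,3
xylose,full_pathway,H,7.5,2.6,31.3,NA,3
xylose,full_pathway,D,NA,NA,31.3,NA,3
ia_glpx,mdh_only,H,52,1,31.3,NA,3
ia_glpx,full_pathway,H,17,1.5,31.3,NA,3
ia_glpx,full_pathway,D,5.3125,0.47,31.3,NA,3
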