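cross_sectional,minimal_atrophy,diffuse_1,diffuse_2,diffuse_3,hs_early_onset,hs_late_onset,cluster_7,cluster_8,hpd_uncertain
diffuse_1,6,12,15,2,1,0,0,1,2
diffuse_2,0,0,0,2,0,0,0,1,0
hippocampal_sparing,0,0,0,0,3,4,0,0,0
limbic_predominant,0,1,0,0,0,0,1,0,1
minimal_atrophy,17,2,0,0,0,1,0,0,0
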