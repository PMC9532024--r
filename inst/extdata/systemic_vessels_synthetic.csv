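name,from,to,r0_mm,length_mm,E_Pa,territory
ascending_aorta,heart,aortic_root,12,40,4e5,NA
aortic_arch,aortic_root,arch,10,30,4e5,NA
descending_aorta,arch,body_junction,9,150,4e5,NA
extracranial_outlet,body_junction,body,9,10,4e5,systemic
l_common_carotid,arch,l_cca_end,3,120,7e5,NA
r_common_carotid,arch,r_cca_end,3,120,7e5,NA
l_internal_carotid,l_cca_end,cow_l,2,130,8e5,NA
r_internal_carotid,r_cca_end,cow_r,2,130,8e5,NA
l_vertebral,arch,vb_junction,1.4,140,8e5,NA
r_vertebral,arch,vb_junction,1.4,140,8e5,NA
basilar,vb_junction,cow_post,1.6,30,1.6e6,NA
root_L-MCA,cow_l,root_L-MCA_end,1.4,30,1.6e6,L-MCA
root_R-MCA,cow_r,root_R-MCA_end,1.4,30,1.6e6,R-MCA
root_L-ACA,cow_l,root_L-ACA_end,1.17,40,1.6e6,L-ACA
root_R-ACA,cow_r,root_R-ACA_end,1.17,40,1.6e6,R-ACA
root_L-PCA,cow_post,root_L-PCA_end,1,35,1.6e6,L-PCA
root_R-PCA,cow_post,root_R-PCA_end,1,35,1.6e6,R-PCA
root_cerebellum,cow_post,root_cerebellum_end,1.2,25,1.6e6,cerebellum
root_brainstem,cow_post,root_brainstem_end,0.7,15,1.6e6,brainstem
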