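case_id,mri_volume_cm3,histo_volume_cm3,mri_ap_cm,histo_ap_cm,mri_cc_cm,histo_cc_cm,mri_lr_cm,histo_lr_cm,n_slides
1,8.45,5.08,3.7,1.9,3.0,3.3,3.4,3.7,7
2,1.60,0.60,2.1,2.6,2.0,1.6,0.9,0.7,8
3,8.20,4.50,4.0,4.2,4.3,2.2,2.2,3.9,8
4,12.60,1.10,3.9,0.7,5.8,3.4,2.8,2.1,9
5,0.60,0.40,2.0,2.0,1.6,1.4,0.4,0.3,12
6,2.20,2.40,2.8,2.7,2.5,2.4,1.3,1.3,12
7,3.90,2.60,3.2,2.7,2.1,1.9,1.6,1.1,16
8,4.00,4.00,3.1,3.2,2.7,2.9,2.0,1.5,21
9,4.90,4.30,2.8,3.5,2.9,2.6,1.8,1.6,11
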