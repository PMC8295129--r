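modality,metric,mean,sd
CBCT,SSIM,0.85,0.05
CBCT,FSIM,0.82,0.03
CBCT,EPR,0.47,0.06
CBCT,EGR,3.0,0.7
CBCT,MAE,109,14
CBCT,NCC,0.997,0.001
CBCT,NM_synthetic,52,13
CBCT,NM_reference,60,16
CBCT,HistCC,0.994,0.003
CT,SSIM,0.94,0.02
CT,FSIM,0.82,0.02
CT,EPR,0.43,0.04
CT,EGR,1.9,0.3
CT,MAE,51,16
CT,NCC,0.980,0.010
CT,NM_synthetic,39,5
CT,NM_reference,39,19
CT,HistCC,0.999,0.002
MRI,SSIM,0.59,0.04
MRI,FSIM,0.51,0.02
MRI,EPR,0.40,0.03
MRI,EGR,1.7,0.2
MRI,MAE,37,6
MRI,NCC,0.86,0.04
MRI,NM_synthetic,25,3
MRI,NM_reference,22,5
MRI,HistCC,0.94,0.03
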