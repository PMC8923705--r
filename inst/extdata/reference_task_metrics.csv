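wavelengths,normalization,det,tar,tvr,acc,dtar,dtvr,dacc
757+800,none,12.00,89.81,75.97,81.58,3.62,17.69,11.99
757+800,clahe,33.53,72.15,79.16,76.32,16.71,38.83,29.86
757+800,proposed,78.89,77.88,97.21,89.38,66.85,76.69,72.71
757+850,none,11.39,74.78,88.71,83.06,2.78,17.08,11.32
757+850,clahe,31.04,62.54,90.82,79.36,16.21,37.12,28.65
757+850,proposed,76.19,71.62,96.52,86.43,58.98,74.38,68.14
800+850,none,11.87,30.41,85.61,63.24,2.88,15.71,10.51
800+850,clahe,34.75,25.81,86.07,61.65,16.39,30.37,24.70
800+850,proposed,79.51,48.66,77.47,65.79,37.35,65.33,53.99
757+800+850,none,11.58,78.35,88.06,84.12,3.07,17.28,11.52
757+800+850,clahe,32.13,64.91,90.03,79.85,16.96,38.05,29.51
757+800+850,proposed,77.11,73.12,96.80,87.21,61.01,75.24,69.47
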