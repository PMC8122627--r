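system,probe,probe_type,solvent,temperature_K,viscosity_Pa_s,freq_MHz,exp_T1_ms,calc_T1_ms,exp_T2_ms,calc_T2_ms,exp_NOE,calc_NOE,reff_A,e_T1,e_T2,e_NOE
R2R,1,CH,DMSO-d6,298.2,2.19e-3,600.1,440.0,449.9,402.6,420.5,2.361,2.308,1.6,2.3,4.4,2.3
R2R,1,CH,DMSO-d6,298.2,2.19e-3,700.0,475.6,497.5,432.9,456.1,2.215,2.150,1.6,4.6,5.4,2.9
BGL,1,CH2,DMSO-d6/D2O 7:3,253,2.82e-2,400,150,177,32.5,31.4,1.03,1.22,1.8,17.8,3.2,18.5
BGL,1,CH2,DMSO-d6/D2O 7:3,253,2.82e-2,600,284,344,30.1,33.1,1.08,1.21,1.8,21.1,10.1,12.2
BGL,1,CH2,DMSO-d6/D2O 7:3,263,1.42e-2,400,117,121,48.0,53.7,1.19,1.26,1.8,3.6,11.8,5.9
BGL,1,CH2,DMSO-d6/D2O 7:3,263,1.42e-2,600,205,219,55.0,61.0,1.10,1.23,1.8,6.9,10.9,12.1
BGL,1,CH2,DMSO-d6/D2O 7:3,293,4.30e-3,400,127,124,106,107,1.86,1.78,1.8,2.0,1.0,4.5
BGL,1,CH2,DMSO-d6/D2O 7:3,293,4.30e-3,600,166,170,128,133,1.58,1.51,1.8,2.6,3.8,4.5
BGL,1,CH2,DMSO-d6/D2O 7:3,293,4.30e-3,900,219,249,152,153,1.45,1.33,1.8,13.6,0.6,8.3
GGM,1,CH,D2O,298.6,1.09e-3,600.13,456.2,453.2,416.6,425.7,2.398,2.299,1.8,0.7,2.2,4.1
GGM,1,CH,D2O,298.6,1.09e-3,699.87,491.1,503.8,447.4,463.6,2.267,2.148,1.8,2.6,3.6,5.3
GGM,2,CH,D2O,298.6,1.09e-3,600.13,491.6,470.0,450.2,444.6,2.466,2.358,1.8,4.4,1.2,4.4
GGM,2,CH,D2O,298.6,1.09e-3,699.87,524.5,521.5,483.9,483.6,2.346,2.203,1.8,0.6,0.1,6.1
TRI,1,CH2,DMSO-d6/D2O 7:3,298,3.66e-3,500,144.79,143.60,111.57,108.21,1.670,1.481,2.2,0.8,3.0,11.3
TRI,1,CH2,DMSO-d6/D2O 7:3,298,3.66e-3,600,167.59,169.40,117.67,118.20,1.460,1.422,2.2,1.1,0.4,2.6
TRI,1,CH2,DMSO-d6/D2O 7:3,298,3.66e-3,700,188.36,197.78,124.55,127.06,1.320,1.385,2.2,5.0,2.0,4.9
LNF,A,CH,DMSO-d6/D2O 7:3,303,1.40e-3,600,305.0,349.5,222.0,213.0,1.460,1.489,3.2,14.6,4.1,2.0
LNF,A,CH,DMSO-d6/D2O 7:3,303,1.40e-3,700,354.0,418.6,244.0,227.9,1.420,1.451,3.2,18.2,6.6,2.2
LNF,B,CH,DMSO-d6/D2O 7:3,303,1.40e-3,600,319.0,336.3,241.0,214.4,1.600,1.423,3.2,5.4,11.0,11.0
LNF,B,CH,DMSO-d6/D2O 7:3,303,1.40e-3,700,366.0,400.3,264.0,229.9,1.530,1.386,3.2,9.4,12.9,9.4
LNF,C,CH,DMSO-d6/D2O 7:3,303,1.40e-3,600,318.0,336.6,225.0,235.9,1.630,1.438,3.2,5.9,4.8,11.8
LNF,C,CH,DMSO-d6/D2O 7:3,303,1.40e-3,700,360.0,395.9,240.0,254.1,1.560,1.392,3.2,10.0,6.9,10.7
LNF,D,CH,DMSO-d6/D2O 7:3,303,1.40e-3,600,372.0,365.8,286.0,275.2,1.740,1.525,3.2,1.7,3.8,12.3
LNF,D,CH,DMSO-d6/D2O 7:3,303,1.40e-3,700,404.0,421.2,302.0,296.7,1.690,1.469,3.2,4.3,1.7,13.1
LNF,E,CH,DMSO-d6/D2O 7:3,303,1.40e-3,600,325.0,390.1,259.0,270.1,1.490,1.728,3.2,20.0,4.3,15.6
LNF,E,CH,DMSO-d6/D2O 7:3,303,1.40e-3,700,374.0,455.5,262.0,289.9,1.500,1.677,3.2,21.8,10.6,11.8
GCY,1,CH2,DMSO-d6/D2O 7:3,323,2.90e-3,400,123.5,130.7,75.00,81.59,1.430,1.458,1.8,5.9,8.8,1.9
GCY,1,CH2,DMSO-d6/D2O 7:3,323,2.90e-3,600,187.0,213.3,85.00,96.58,1.330,1.400,1.8,14.1,13.6,5.3
GCY,1,CH2,DMSO-d6/D2O 7:3,323,2.90e-3,900,314.5,370.3,110.9,109.4,1.250,1.384,1.8,17.7,1.3,10.7
GCY,1,CH2,DMSO-d6/D2O 7:3,343,2.30e-3,400,134.1,132.5,107.2,96.8,1.630,1.498,1.8,1.1,9.7,8.1
GCY,1,CH2,DMSO-d6/D2O 7:3,343,2.30e-3,600,183.8,203.6,130.1,117.3,1.510,1.405,1.8,10.8,9.9,6.9
GCY,1,CH2,DMSO-d6/D2O 7:3,343,2.30e-3,900,274.0,335.3,154.8,137.0,1.330,1.366,1.8,22.4,11.5,2.7
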