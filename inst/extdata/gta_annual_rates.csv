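habitat,variable,estimate,lower,upper
heathland,faecal_N_import,3.03,2.32,3.74
heathland,total_N_import,4.91,3.81,6.01
heathland,N_export,18.81,9.91,27.71
heathland,delta_N,-13.90,-22.87,-4.93
heathland,P_import,0.44,0.24,0.64
heathland,P_export,1.52,0.81,2.23
heathland,delta_P,-1.08,-1.82,-0.34
heathland,dung_mass,154.8,126.2,183.4
grassland,faecal_N_import,2.58,2.36,2.79
grassland,total_N_import,4.92,4.48,5.36
grassland,N_export,34.41,22.69,46.14
grassland,delta_N,-29.50,-41.23,-17.76
grassland,P_import,0.73,0.66,0.81
grassland,P_export,4.02,2.54,5.51
grassland,delta_P,-3.29,-4.78,-1.80
grassland,dung_mass,97.1,91.8,102.4
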