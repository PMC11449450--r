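muscle,mass_g,muscle_length_mm,pennation_deg,fibre_length_mm
digastric,0.691,34.75,9.81,11.59
AZM,1.8,20,20,6.5
PDM,2.5,24,22,8.0
PT,1.8,22,18,7.0
SM,3.0,30,25,9.5
PZM,1.5,18,15,6.0
ST,1.4,28,12,7.5
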