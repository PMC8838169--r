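agent,concentration_pct,strain_min,strain_max,observation_s
glycerol,7,NA,0.0025,600
glycerol,25,-0.006,NA,600
glycerol,35,-0.14,0.20,600
glycerol,100,-0.36,0.40,600
iohexol_omnipaque,39.2,-0.06,0.15,600
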