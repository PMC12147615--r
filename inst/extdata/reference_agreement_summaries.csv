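# Published Bland-Altman summaries (one decimal) from a validation study of
# the mallet-inclinometer DTM-range technique against optical motion capture
# (42 healthy adults, two raters, three trials). p_gamma "<.001" is stored
# as 0.001.
scheme,side,mean_difference,ci_low,ci_high,gamma,p_gamma,bias_pct,loa_low_pct,loa_high_pct
first,dominant,21.9,19.0,24.8,0.45,0.003,35.9,9.4,62.4
first,nondominant,20.1,17.2,23.1,0.50,0.001,30.7,7.2,54.2
first-second,dominant,22.1,19.5,24.7,0.54,0.001,35.2,13.2,57.2
first-second,nondominant,20.8,17.6,23.9,0.46,0.002,31.4,6.2,56.6
first-third,dominant,22.6,19.9,25.4,0.57,0.001,35.5,14.2,56.9
first-third,nondominant,20.8,17.9,23.7,0.51,0.001,31.1,9.1,53.1
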