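material,density,z_over_a,z_eff_coh,elements
water,1,0.55508,5.84724734203501,H:0.111894;O:0.888106
air,0.0012048,0.49919,7.45773248442369,C:0.000124;N:0.755268;O:0.231781;Ar:0.012827
pmma,1.18,0.53937,5.4171900165123,H:0.080538;C:0.599848;O:0.319614
titanium,4.5,0.45961,22,Ti:1.000000
silver,10.53,0.4357,47,Ag:1.000000
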