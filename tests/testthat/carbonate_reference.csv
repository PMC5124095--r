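a_t,dic,temperature_c,salinity,ph_total,pco2_uatm,omega_arag,co3_umol_kg
2300,1900,29,35,8.141310,296.1167,4.523325,279.375072
2300,2050,29,35,7.897750,595.5861,2.963604,183.041686
2300,2150,29,35,7.689197,1040.3143,1.981226,122.366871
2250,1980,29,34.5,7.947734,508.9587,3.157719,194.341749
2350,2000,28,35.5,8.067090,376.7827,3.981232,248.105602
2400,2250,29.5,35,7.672485,1135.3727,2.038570,125.561049
2300,2200,26,34,7.615561,1258.6913,1.503439,93.692524
2200,1950,30,33,7.922620,539.7254,2.999036,181.680886
2450,2100,24,36,8.105429,355.6363,3.923661,250.081581
2320,2280,29,35,7.396494,2199.6181,1.088206,67.211079
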