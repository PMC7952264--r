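medium,unit,n,pct_above_lod,lod_low,lod_high,mean,median,sd,source
dairy,mg/g,5220,14.8,3.00e-08,1.00e-06,2.55e-06,2.00e-06,7.45e-03,"USDA PDP 1994-2010, endosulfan sulfate, positive detects only"
meat,mg/g,1176,1.8,3.00e-07,2.00e-06,1.48e-05,4.80e-06,2.67e-02,"USDA PDP 1994-2010, endosulfan sulfate, positive detects only"
fish,mg/g,147,96.6,1.00e-06,1.00e-06,5.26e-06,2.70e-06,6.03e-03,"USDA PDP 1994-2010, endosulfan sulfate, positive detects only"
vegetables,mg/g,61805,11.7,2.00e-06,4.00e-04,3.80e-05,2.00e-05,7.49e-02,"USDA PDP 1994-2010, endosulfan sulfate, positive detects only"
fruit,mg/g,3987,14.6,1.00e-06,6.80e-02,2.16e-05,1.20e-05,2.63e-02,"USDA PDP 1994-2010, endosulfan sulfate, positive detects only"
grains,mg/g,558,0.2,1.00e-06,1.00e-06,2.00e-06,2.00e-06,0.00e+00,"USDA PDP 1994-2010, endosulfan sulfate, positive detects only"
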