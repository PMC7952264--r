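medium,unit,n,pct_above_lod,lod_low,lod_high,mean,median,sd,source
vegetables,mg/g,21355,4.4,2.00e-06,4.00e-04,2.53e-05,1.40e-05,3.49e-05,"USDA PDP 2011-2016, endosulfan sulfate, positive detects only"
fruit,mg/g,7415,1.5,1.00e-06,6.80e-02,2.26e-05,1.90e-05,1.28e-05,"USDA PDP 2011-2016, endosulfan sulfate, positive detects only"
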