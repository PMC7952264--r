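medium,unit,n,pct_above_lod,lod_low,lod_high,mean,median,sd,source
soil,mg/g,329,NA,NA,NA,3.41e-01,1.80e-01,1.90e-01,"Gulson et al. 2014 (household soil, AU)"
dust,mg/g,661,NA,NA,NA,2.22e-01,1.60e-01,2.45e-01,"Gulson et al. 2014 (household dust, AU)"
water,mg/mL,416,57,9.00e-07,9.00e-07,6.35e-05,2.80e-06,2.19e-04,"Lindsey et al. 2017 (USGS NAWQA 2013-2014)"
breastmilk,mg/mL,20,NA,NA,NA,2.71e-06,NA,1.12e-06,"Klein et al. 2017 (MA breastmilk samples)"
dairy,mg/g,759,25,3.00e-04,4.00e-04,8.19e-04,1.30e-04,1.46e-03,"FDA Total Diet Study 2006-2013"
meat,mg/g,1725,65,3.00e-04,4.00e-04,1.66e-03,1.70e-03,1.06e-03,"FDA Total Diet Study 2006-2013"
fish,mg/g,224,46,3.00e-03,3.00e-03,9.63e-04,4.20e-04,1.10e-03,"FDA Total Diet Study 2006-2013"
vegetables,mg/g,1631,99,2.00e-04,4.00e-04,1.79e-03,1.20e-03,1.31e-03,"FDA Total Diet Study 2006-2013"
fruit,mg/g,1055,79,2.00e-04,4.00e-04,1.62e-03,4.45e-04,3.45e-03,"FDA Total Diet Study 2006-2013"
grains,mg/g,1484,99,3.00e-04,4.00e-04,7.34e-03,4.90e-03,7.14e-03,"FDA Total Diet Study 2006-2013"
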