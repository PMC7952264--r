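medium,unit,n,pct_above_lod,lod_low,lod_high,mean,median,sd,source
soil,mg/g,6,100,NA,NA,9.39e-03,8.63e-03,2.19e-03,"Lin et al. 2009; LOD printed as 0.2 ug/mL in 1-butanol buffer (solvent phase, not stored)"
dust,mg/g,11,100,NA,NA,9.73e-02,7.31e-02,1.11e-01,"Subedi et al. 2017; LOD printed as 0.14-278 ng/mL in hexane:acetone extract (solvent phase, not stored)"
water,mg/mL,15,13,1.76e-06,1.76e-06,2.56e-06,NA,NA,"Loraine et al. 2006 (finished drinking water, CA)"
breastmilk,mg/mL,21,100,NA,NA,7.07e-04,1.91e-04,8.87e-04,"Hartle et al. 2018; sum of metabolite means (MEHP, MEOHP, MEHHP); per-metabolite LODs 6.18e-7, 1.03e-7, 1.03e-7 mg/mL"
dairy,mg/g,11,100,3.70e-06,3.70e-06,1.26e-04,6.97e-05,1.25e-04,"Schecter et al. 2013 (NY food survey)"
meat,mg/g,13,69,3.70e-06,3.70e-06,1.01e-04,7.00e-06,3.18e-04,"Schecter et al. 2013 (NY food survey)"
fish,mg/g,5,80,3.70e-06,3.70e-06,3.14e-05,3.96e-05,2.60e-05,"Schecter et al. 2013 (NY food survey)"
vegetables,mg/g,5,40,3.70e-06,3.70e-06,5.09e-06,1.85e-06,8.70e-06,"Schecter et al. 2013 (NY food survey)"
fruit,mg/g,5,40,3.70e-06,3.70e-06,5.09e-06,1.85e-06,8.70e-06,"Schecter et al. 2013 (NY food survey)"
grains,mg/g,7,100,3.70e-06,3.70e-06,6.16e-05,5.06e-05,4.25e-05,"Schecter et al. 2013 (NY food survey)"
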