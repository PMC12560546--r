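chr01	chr01_m001
chr01	chr01_m002
chr01	chr01_m003
chr01	chr01_m004
chr01	chr01_m005
chr01	chr01_m006
chr01	chr01_m007
chr01	chr01_m008
chr01	chr01_m009
chr01	chr01_m010
chr02	chr02_m001
chr02	chr02_m002
chr02	chr02_m003
chr02	chr02_m004
chr02	chr02_m005
chr02	chr02_m006
chr02	chr02_m007
chr02	chr02_m008
chr02	chr02_m009
chr02	chr02_m010
chr03	chr03_m001
chr03	chr03_m002
chr03	chr03_m003
chr03	chr03_m004
chr03	chr03_m005
chr03	chr03_m006
chr03	chr03_m007
chr03	chr03_m008
chr03	chr03_m009
chr03	chr03_m010
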