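individual	chr01_m001	chr01_m002	chr01_m003	chr01_m004	chr01_m005	chr01_m006	chr01_m007	chr01_m008	chr01_m009	chr01_m010	chr02_m001	chr02_m002	chr02_m003	chr02_m004	chr02_m005	chr02_m006	chr02_m007	chr02_m008	chr02_m009	chr02_m010	chr03_m001	chr03_m002	chr03_m003	chr03_m004	chr03_m005	chr03_m006	chr03_m007	chr03_m008	chr03_m009	chr03_m010
EX_01	A	A	H	-	H	B	H	H	A	A	H	H	H	H	H	H	H	H	H	H	H	H	H	H	B	B	B	B	B	B
EX_02	H	H	H	H	B	B	A	A	H	H	H	H	H	B	H	H	H	H	H	B	-	H	H	-	H	H	H	H	H	H
EX_03	H	H	H	H	B	H	H	H	H	H	H	H	H	H	H	A	A	A	A	A	H	H	H	H	B	B	B	B	B	B
EX_04	B	B	H	H	H	H	B	B	B	B	H	A	A	A	A	A	A	A	A	H	A	A	A	A	A	H	H	H	H	H
EX_05	B	H	H	H	H	A	A	A	A	H	B	-	B	B	B	B	B	B	H	H	-	A	A	A	A	A	A	H	H	H
EX_06	B	H	A	-	-	A	A	A	A	A	A	H	B	B	H	H	H	B	B	B	H	H	-	B	B	H	H	H	H	H
EX_07	B	B	B	H	H	H	H	B	B	B	H	H	H	H	A	A	A	A	A	A	H	H	H	-	H	H	H	H	H	B
EX_08	B	B	B	B	B	B	B	B	B	B	A	A	A	A	H	H	H	-	H	H	H	H	H	H	H	H	H	A	A	A
EX_09	H	H	H	H	H	A	A	A	A	A	H	H	H	H	H	H	H	B	B	B	A	A	A	A	A	A	A	A	A	A
EX_10	A	A	H	B	B	B	B	B	B	B	H	H	-	H	H	A	A	A	A	A	H	H	B	H	H	H	A	A	H	H
EX_11	B	B	B	B	B	B	B	B	H	A	A	A	A	A	A	H	H	-	H	H	H	H	H	H	-	H	H	H	H	H
EX_12	H	H	A	H	H	H	H	H	H	B	B	B	B	B	B	B	B	B	B	B	A	A	H	H	H	H	H	H	B	-
EX_13	B	B	B	-	H	B	B	-	H	H	B	B	B	B	H	H	H	H	H	H	H	B	B	B	B	B	H	H	H	H
EX_14	B	B	H	H	B	B	B	B	B	B	H	H	H	H	H	H	H	B	H	H	H	A	A	-	A	A	A	H	H	H
EX_15	B	B	B	B	B	B	B	H	H	H	A	A	A	A	H	H	H	H	H	H	A	A	A	A	A	A	A	A	A	A
EX_16	B	B	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	A	H	H	H	H
EX_17	A	-	B	B	H	H	H	H	H	B	H	A	A	A	A	A	A	A	H	H	H	H	H	H	H	H	A	A	A	A
EX_18	B	B	B	B	B	B	B	B	B	B	H	H	H	H	H	H	H	H	A	H	A	H	H	H	H	H	H	H	H	H
EX_19	A	A	A	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	B
EX_20	H	H	H	H	H	H	H	B	B	B	B	H	H	H	A	A	A	A	A	A	H	H	H	H	H	H	H	H	A	A
EX_21	H	H	H	H	H	B	B	H	A	A	B	B	B	B	B	B	B	B	B	B	H	H	H	H	H	H	H	H	H	H
EX_22	B	H	H	H	H	H	H	H	H	B	B	B	B	B	B	B	B	B	H	-	H	H	H	H	H	H	A	H	H	H
EX_23	A	A	A	A	A	A	H	H	-	H	H	H	H	H	A	A	A	A	H	H	H	H	A	A	A	H	H	H	H	B
EX_24	H	H	H	H	H	A	A	A	A	A	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	-	H	H
EX_25	B	B	B	B	B	B	B	B	B	B	H	B	B	B	B	B	H	H	H	H	A	A	A	-	A	A	H	A	A	A
EX_26	H	H	H	H	H	H	A	A	A	A	H	H	B	H	-	H	B	B	B	B	H	H	B	B	B	H	H	H	H	-
EX_27	B	H	H	H	H	H	A	A	A	A	-	A	A	A	A	A	A	A	A	A	B	B	B	B	B	B	B	B	B	B
EX_28	H	A	A	A	A	A	H	H	A	A	B	B	H	H	H	H	H	H	H	H	B	B	B	-	B	H	H	H	A	A
EX_29	H	-	B	B	H	H	H	H	H	H	H	-	H	H	A	A	A	H	H	B	A	A	A	A	A	H	H	H	H	H
EX_30	H	H	H	H	B	-	H	H	H	H	A	A	A	H	H	B	B	B	B	B	B	B	B	B	B	B	B	B	B	B
EX_31	H	H	H	H	H	B	H	B	B	B	H	H	H	H	H	H	H	B	B	B	A	A	H	H	H	B	B	B	B	B
EX_32	A	A	A	A	H	H	H	H	H	A	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H
EX_33	B	B	B	B	B	H	H	H	H	H	H	H	H	H	H	H	H	H	H	A	A	A	A	A	A	A	A	H	H	H
EX_34	B	B	H	H	H	H	H	H	H	H	B	B	B	B	B	B	H	H	H	H	A	A	A	A	A	A	A	H	H	H
EX_35	B	B	B	B	B	B	B	B	B	B	H	H	H	H	H	H	A	A	A	A	B	B	B	B	B	B	B	B	H	H
EX_36	B	B	B	B	B	B	B	H	H	B	B	B	H	H	H	H	H	H	H	B	A	A	A	A	A	A	A	H	H	H
EX_37	H	H	A	A	-	A	A	A	A	A	A	A	A	A	A	A	A	H	B	B	B	B	H	H	H	H	H	H	H	H
EX_38	A	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	H	B	B	B	B	B	B	B	B	B	B
EX_39	H	H	H	H	H	A	A	A	A	A	H	H	H	H	H	H	H	H	H	H	H	H	H	B	B	B	B	B	B	B
EX_40	A	A	A	A	A	-	A	A	A	B	A	A	H	H	H	H	H	H	H	H	A	A	A	A	H	H	H	H	A	A
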