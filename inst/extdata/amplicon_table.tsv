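amplicon	direction	chromosome	start_rel	end_rel	length	cpg_count	left_primer	right_primer
PTPRS_amp03	F	2	−2509	−2162	348	9	aggaagagagTTGGTTATTTTTGTTTTTAAAGGGTT	cagtaatacgactcactatagggagaaggctAAAAAAAACATCCACACAAAATCAC
PTPRS_amp09	F	2	−2186	−1700	487	8	aggaagagagGTGATTTTGTGTGGATGTTTTTTTT	cagtaatacgactcactatagggagaaggctTAATTCTAACTCCCAAAATACCCAA
PTPRS_amp12	F	2	−1873	−1545	329	10	aggaagagagGGTTTGATTGTGTGTTTTTTGAGAT	cagtaatacgactcactatagggagaaggctAATTTCCACTTTAACCAAAACCAA
PTPRS_amp16	F	2	−1570	−1099	472	20	aggaagagagGTTTGGTTTTGGTTAAAGTGGAAAT	cagtaatacgactcactatagggagaaggctATTTAACCACCAAATAAATCTTCCC
PTPRS_amp17	F	2	−1226	−890	337	11	aggaagagagTGGGGTTATGTGGTTGTATTTTTTA	cagtaatacgactcactatagggagaaggctAACCTACACCACAACTCAAATCAAT
PTPRS_amp25	F	2	−322	122	444	15	aggaagagagGAGGGTTAGGTTTTTATATAATTTTGGA	cagtaatacgactcactatagggagaaggctAACACACACAAAACCAAATACTCAC
PTPRS_amp30	R	2	−2486	−2081	406	11	aggaagagagAGGGTTATAGTGGGGTAGATAATGT	cagtaatacgactcactatagggagaaggctACCCAAAATAAAAACACAAAACAAA
PTPRS_amp37	R	2	−1561	−1326	236	7	aggaagagagGTTGTTATAATGGGAATTTTTGAAT	cagtaatacgactcactatagggagaaggctAAAACCATATAACTACACCTCCCAC
PTPRS_amp41	R	2	−1033	−730	304	9	aggaagagagGGGATTAGGGTTTTTATAAAGGGAT	cagtaatacgactcactatagggagaaggctTCAAAACTAAAATCTAAACTTCATCACAA
PPP1R3E_amp01	F	7	−87	135	222	12	aggaagagagGGGGAGGTAGAGTGGTTTTATTTT	cagtaatacgactcactatagggagaaggctCACTAACCTTCAACTTCCAAAATCT
PPP1R3E_amp07	F	7	−12	135	140	11	aggaagagagATGGGGAGTTATTTGTTAGAGGGTA	cagtaatacgactcactatagggagaaggctCTTCAACTTCCAAAATCTTAAACCA
PPP1R3E_amp12	F	7	188	833	646	72	aggaagagagTTGGAGGTGATAGTAAGGAGAGTAAGAAAT	cagtaatacgactcactatagggagaaggctCAAAAACCAACCCAAAATTAAAAAT
SORT1_amp04	F	4	−702	−197	506	20	aggaagagagTTTTTGTAGAAGAGGAAGATGAGTGA	cagtaatacgactcactatagggagaaggctCCTCCTACTTAAAAAATCCTAAATTC
WNT5B_amp24	R	5	−1735	−1369	367	9	aggaagagagTTTGGGATTAGAGATGGAGTAGAGA	cagtaatacgactcactatagggagaaggctACTATCCTAAAAAACAAAAACCCCA
WNT5B_amp28	R	5	−1180	−821	360	11	aggaagagagATTTTGGAGTAAGTTTTTGGAAAGG	cagtaatacgactcactatagggagaaggctCACACACCTACCTATTAATACCCCC
WNT5B_amp31	R	5	−845	−462	384	10	aggaagagagTGGAGTTGAAAGTAATTGGTAAGTTG	cagtaatacgactcactatagggagaaggctCCTTTCCAAAAACTTACTCCAAAAT
WNT5B_amp38	R	5	−487	−166	322	8	aggaagagagGGAGAGTTTGTTTTTTTAGGAAAGG	cagtaatacgactcactatagggagaaggctCAACTTACCAATTACTTTCAACTCCA
PDE9A_amp05	F	13	−1855	−1392	464	11	aggaagagagGGAGGGTTTAGGGAGATATTTGATA	cagtaatacgactcactatagggagaaggctCAAATAAAAACAAAAAACCCCTCTT
PDE9A_amp14	F	13	−1342	−890	453	20	aggaagagagGGAGGTAGAGGGGGTTGTTAGTTAG	cagtaatacgactcactatagggagaaggctTTAACCCACAAAAAAAACTATCCC
PDE9A_amp15	F	13	−1018	−680	339	22	aggaagagagTTTTGTTGTGTTGATATTTGTTTGG	cagtaatacgactcactatagggagaaggctAAAAACTAACAACTTTTATATAACCCC
PDE9A_amp17	F	13	−608	−202	407	12	aggaagagagTTTGTTTTTTGAGAGTTTGGTAAAG	cagtaatacgactcactatagggagaaggctTCAAACCAAAAACCATAAAATTACAA
PDE9A_amp24	R	13	−2258	−1831	428	35	aggaagagagTGTTAAGTGTTTTTTTGGGTTTTTT	cagtaatacgactcactatagggagaaggctCCTCAACATAAACTTATCCATCCTC
PDE9A_amp25	R	13	−1907	−1548	360	11	aggaagagagTGTATTGGTTATAGAGTTGGGAGGA	cagtaatacgactcactatagggagaaggctATCACAAACCAAACCAAACTCC
PDE9A_amp34	R	13	−1572	−1129	444	13	aggaagagagGTGGTTGGTTAGGGTTTTTTTTAAG	cagtaatacgactcactatagggagaaggctTCCTCCCAACTCTATAACCAATACA
PDE9A_amp41	R	13	−230	63	293	14	aggaagagagTTATTGAAGGTAAAAGTAGGGTTGG	cagtaatacgactcactatagggagaaggctAACCTACAACCCCATAATTCCTAAC
FGFR4_amp04	F	2	−2675	−2178	498	10	aggaagagagTGGTTTTGAGAGGTGTAGTTATTTG	cagtaatacgactcactatagggagaaggctAACAAAACCCAATCCACACTATTTA
FGFR4_amp26	R	2	−2989	−2740	350	22	aggaagagagGGGATTTTGGATAAATGATTGTATTT	cagtaatacgactcactatagggagaaggctCCTCCCAACACTAAAAACCTAAAC
FGFR4_amp38	R	2	−2013	−1677	337	5	aggaagagagTATTATTTGGGGTTGGGTAATAGGT	cagtaatacgactcactatagggagaaggctCCCAAACTTATCATTTTTAAAACCC
FGFR4_amp44	R	2	−1392	−893	500	5	aggaagagagGGGTTAAATTTAGGGTTAGGGGTTA	cagtaatacgactcactatagggagaaggctATCCTCAAAATAATCCTAAAAAAAA
FGFR4_amp46	R	2	−903	−494	410	6	aggaagagagTTTGGATGTTATTTGATTTGATTTT	cagtaatacgactcactatagggagaaggctAAATTTAACCCCTAACCCAAAAACT
FABP5_amp09	F	4	217	701	485	28	aggaagagagGTGTTGGGTTTAGGGGTTAGGTAG	cagtaatacgactcactatagggagaaggctAAAAACCTAATCCAAACTCTCTAAAAAA
FABP5_amp14	F	4	670	1068	399	23	aggaagagagGAAATTTTTTAGAGAGTTTGGATTAGG	cagtaatacgactcactatagggagaaggctAATTAAAAAACAACCCCAAAAAAAC
FABP5_amp19	F	4	1123	1495	373	4	aggaagagagTTAAGGATGAGTGATTTTTAGGTAGGA	cagtaatacgactcactatagggagaaggctCAAAAAACCAACCTTAACCAACTAA
FABP5_amp28	R	4	−987	−562	426	5	aggaagagagTTTAGTTTAATTGGGGTTTTTGGAT	cagtaatacgactcactatagggagaaggctTTACCTCCACCAAAATAACTACCCT
FABP5_amp29	R	4	−656	−336	321	8	aggaagagagATGTTTTTTTTGGGTTAGAGGATTT	cagtaatacgactcactatagggagaaggctCTTCCTAAAACTTTTCCAACTACCC
FABP5_amp30	R	4	−361	91	452	48	aggaagagagATTAGTTGTTGGATGGAGGTTATGG	cagtaatacgactcactatagggagaaggctTAAATCCTCTAACCCAAAAAAAACA
FABP5_amp33	R	4	189	618	430	22	aggaagagagTTAGGAATAAAAGATGTTGTAGGGTG	cagtaatacgactcactatagggagaaggctAACTATATCCCTAAAACACCCCCTC
FABP5_amp38	R	4	1044	1425	382	5	aggaagagagGGATTTAGGTTTTTGTAGTGATTTTTG	cagtaatacgactcactatagggagaaggctACCCTCCTAAAACTATTTTCTAACTAA
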