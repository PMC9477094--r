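drug,gene,phenotype,frequency,action,risk_untested,risk_tested
Azathioprine,TPMT,TPMT EM,0.912,none,0.00194103466113,0.00194103466113
Azathioprine,TPMT,TPMT IM,0.087,dose_adjust,0.00554103466113,0.00194103466113
Azathioprine,TPMT,TPMT PM,0.001,dose_adjust,0.0116410346611,0.00194103466113
Capecitabine,DPYD,DPYD GAS 0,0.001,alternative_drug,0.00992546763957,0.00232546763957
Capecitabine,DPYD,DPYD GAS 0.5/PHENO,0,dose_adjust,0.00812546763957,0.00232546763957
Capecitabine,DPYD,DPYD GAS 1.0,0.018,dose_adjust,0.00622546763957,0.00232546763957
Capecitabine,DPYD,DPYD GAS 1.5,0.054,dose_adjust,0.00472546763957,0.00232546763957
Capecitabine,DPYD,DPYD GAS 2.0,0.925,none,0.00232546763957,0.00232546763957
Clopidogrel,CYP2C19,CYP2C19 EM,0.673,none,0.0294910823263,0.0294910823263
Clopidogrel,CYP2C19,CYP2C19 IM,0.245,dose_adjust,0.043363626019,0.0294910823263
Clopidogrel,CYP2C19,CYP2C19 PM,0.037,alternative_drug,0.0318031729418,0.0294910823263
Clopidogrel,CYP2C19,CYP2C19 UM,0.045,none,0.0294910823263,0.0294910823263
Fluorouracil (systemic),DPYD,DPYD GAS 0,0.001,alternative_drug,0.00992496611849,0.00232496611849
Fluorouracil (systemic),DPYD,DPYD GAS 0.5/PHENO,0,dose_adjust,0.00812496611849,0.00232496611849
Fluorouracil (systemic),DPYD,DPYD GAS 1.0,0.018,dose_adjust,0.00622496611849,0.00232496611849
Fluorouracil (systemic),DPYD,DPYD GAS 1.5,0.054,dose_adjust,0.00472496611849,0.00232496611849
Fluorouracil (systemic),DPYD,DPYD GAS 2.0,0.925,none,0.00232496611849,0.00232496611849
Irinotecan,UGT1A1,UGT1A1 *1/*1,0.43,none,0.00156777231007,0.00156777231007
Irinotecan,UGT1A1,UGT1A1 *1/*28,0.466,none,0.00156777231007,0.00156777231007
Irinotecan,UGT1A1,UGT1A1 *28/*28,0.101,dose_adjust,0.00396777231007,0.00156777231007
Irinotecan,UGT1A1,UGT1A1 IM,0.002,none,0.00156777231007,0.00156777231007
Irinotecan,UGT1A1,UGT1A1 PM,0.001,dose_adjust,0.00396777231007,0.00156777231007
Mercaptopurine,TPMT,TPMT EM,0.912,none,0.00192790385852,0.00192790385852
Mercaptopurine,TPMT,TPMT IM,0.087,dose_adjust,0.00552790385852,0.00192790385852
Mercaptopurine,TPMT,TPMT PM,0.001,dose_adjust,0.0116279038585,0.00192790385852
Tioguanine,TPMT,TPMT EM,0.912,none,0.00195460525578,0.00195460525578
Tioguanine,TPMT,TPMT IM,0.087,dose_adjust,0.00555460525578,0.00195460525578
Tioguanine,TPMT,TPMT PM,0.001,dose_adjust,0.0116546052558,0.00195460525578
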