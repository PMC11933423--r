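patient_id	outcome_pct
pt_01	90
pt_02	96.5
pt_03	-7.2
pt_04	100
pt_05	55
pt_06	91
pt_07	62
pt_08	97
pt_09	80
pt_10	-198.1
pt_11	93
pt_12	66.5
pt_13	98
pt_14	85
pt_15	94
pt_16	70
pt_17	99
pt_18	96
pt_19	75
pt_20	100
pt_21	58
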