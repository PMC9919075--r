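# direction: zone_salmonella=higher_is_active zone_bsubtilis=higher_is_active zone_kpneumoniae=higher_is_active zone_ecoli=higher_is_active zone_saureus=higher_is_active zone_paeruginosa=higher_is_active ic50_amylase=lower_is_active ic50_glucosidase=lower_is_active
sample_id	zone_salmonella	zone_bsubtilis	zone_kpneumoniae	zone_ecoli	zone_saureus	zone_paeruginosa	ic50_amylase	ic50_glucosidase
S1	9.78	12.06	10.33	10.96	10.56	10.15	258.93	2.41
S2	9.41	9.29	12.21	10.94	11.51	10.96	160.67	2.01
S3	8.00	10.51	9.42	8.47	8.75	8.92	394.17	3.84
S4	10.97	13.14	13.29	14.74	10.66	13.01	180.73	2.88
S5	8.12	7.14	8.22	8.87	8.58	7.97	596.93	3.60
S6	7.28	7.28	7.05	6.80	7.11	6.35	NA	99.21
S7	7.71	6.96	6.59	7.15	8.60	6.94	NA	122.57
S8	8.17	12.74	9.86	11.50	10.64	9.98	1193.00	10.24
S9	8.37	13.03	10.76	11.29	9.87	10.66	250.10	2.36
S10	9.55	13.14	10.96	11.30	10.32	10.90	261.23	1.65
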