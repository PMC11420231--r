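individual_id	tomb	phase	method	sex	age_at_death	radiocarbon_bp	cal_68_bc	cal_95_bc
PAN-001	3	Phase A	Osteology	M	Adult (26-40)	3985 +/- 24	2565-2470	2570-2465
PAN-002	3	Phase A	Osteology	M	Adult (41-60)	3838 +/- 24	2340-2210	2450-2200
PAN-003	3	Phase A	Osteology	F	Adult (26-40)	3969 +/- 25	2560-2465	2575-2350
PAN-004	3	Phase B	Osteology	PF	Adult (26-40)	x	x	x
PAN-005	3	Phase B	Osteology	PF	Adult (41-60)	x	x	x
PAN-006	3	Phase B	Osteology	F	Adult (26-40)	x	x	x
PAN-007	3	Phase B	Osteology	PM	Adult	x	x	x
PAN-008	3	Phase B	Proteomics	F	Non-adult (7.5-8.5)	4705 +/- 23	3520-3380	3620-3375
PAN-009	3	Phase B	Proteomics	F	Non-adult (16.5)	4719 +/- 25	3605-3380	3625-3380
PAN-010	7	x	Osteology	PM	Adult	x	x	x
PAN-011	10	Phase A	Osteology	PM	Adult (41-60)	3899 +/- 24	2465-2345	2470-2300
PAN-012	10	Phase A	Osteology	M	Adult (26-40)	x	x	x
PAN-013	10	Phase A	Osteology	F	Adult (18-25)	x	x	x
PAN-014	10	Phase A	Osteology	PF	Adult	x	x	x
PAN-015	10	Phase A	aDNA	PF	Adult	4019 +/- 34	2570-2490	2620-2470
PAN-016	10	Phase A	aDNA	F	Adult	4026 +/- 34	2580-2490	2830-2470
PAN-017	10	Phase A	aDNA	F	Adult	4025 +/- 32	2580-2490	2623-2470
PAN-018	10	Phase A	aDNA	F	Adult	4013 +/- 34	2570-2490	2620-2470
PAN-019	10	Phase B	aDNA	F	Adult	4072 +/- 34	2830-2500	2860-2490
PAN-020	10	Phase A	aDNA	PM	Adult	3958 +/- 34	2570-2410	2570-2350
PAN-021	10	Phase A	aDNA	PF	Adult	4059 +/- 24	2625-2495	2835-2490
PAN-022	10	Phase B	aDNA	PM	Adult	4077 +/- 24	2835-2570	2850-2495
PAN-023	10	Phase B	aDNA	M	Adult	4074 +/- 21	2835-2570	2840-2495
PAN-024	10	Phase B	aDNA	M	Adult	4074 +/- 24	2835-2570	2850-2490
PAN-025	11	Phase A	Osteology	F	Adult (41-60)	3689 +/- 29	2140-2030	2200-1970
PAN-026	11	Phase A	Osteology	F	Adult (26-40)	3907 +/- 29	2465-2350	2470-2300
PAN-027	11	Phase A	Osteology	M	Adult (26-40)	3775 +/- 29	2280-2140	2290-2050
PAN-028	11	Phase A	Osteology	PF	Adult	3973 +/- 29	2570-2465	2580-2350
PAN-029	11	Phase A	Osteology	PM	Adult	3951 +/- 29	2560-2350	2570-2340
PAN-030	11	Phase A	Osteology	F	Adult (41-60)	3929 +/- 29	2470-2350	2560-2300
PAN-031	11	Phase B	Osteology	PF	Adult (41-60)	x	x	x
PAN-032	11	Phase B	Osteology	PF	Adult	x	x	x
PAN-033	11	Phase B	Proteomics	M	Non-adult (7.5-8.5)	x	x	x
PAN-034	11	Phase B	Proteomics	F	Non-adult (9.5-11.5)	x	x	x
PAN-035	15	Phase B	Osteology	M	Adult (41-60)	4589 +/- 28	3490-3350	3500-3120
PAN-036	15	Phase B	Osteology	PM	Adult (18-25)	4247 +/- 28	2910-2880	2910-2710
PAN-037	15	Phase B	Osteology	PF	Adult (41-60)	4548 +/- 28	3370-3120	3370-3100
PAN-038	15	Phase B	Osteology	M	Adult (41-60)	4570 +/- 28	3370-3140	3490-3110
PAN-039	15	Phase B	Osteology	PF	Adult (18-25)	4567 +/- 28	3370-3140	3490-3110
PAN-040	15	Phase B	Osteology	PM	Adult (18-25)	4651 +/- 29	3500-3370	3520-3370
PAN-041	15	Phase B	Osteology	F	Adult (18-25)	x	x	x
PAN-042	15	Phase B	Proteomics	F	Non-adult (12.5-13.5)	4519 +/- 28	3350-3110	3360-3100
PAN-043	15	Phase B	Proteomics	F	Non-adult (11.5-12.5)	4554 +/- 28	3370-3130	3480-3100
PAN-044	15	Phase B	Proteomics	F	Non-adult (16.5)	4407 +/- 29	3090-2930	3310-2920
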