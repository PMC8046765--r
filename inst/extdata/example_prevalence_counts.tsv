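# Example three-digit ICD-9 prevalence counts for a 2210-patient screening
# cohort, used to exercise the prevalence-percentage arithmetic.
code3	n_encounters	n_patients
V65	51916	2122
401	64917	1999
V04	14014	1954
272	33663	1803
V68	16087	1737
780	17167	1678
V72	10712	1624
786	15210	1615
366	14733	1580
367	13642	1563
719	12373	1531
V58	37390	1520
V70	5408	1392
715	17679	1376
V57	25701	1353
724	16596	1292
782	5697	1275
V81	8361	1249
600	10435	1204
389	11075	1191
530	11930	1175
427	31419	1136
702	9129	1126
211	4203	1124
414	21975	1105
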