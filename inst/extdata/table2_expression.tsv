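name	accession	mean_tpm_5p	mean_tpm_3p
mir-10399	LR745789	14.04	NA
mir-1246	LR594712	0.96	NA
mir-1248	LR594713	2.55	NA
mir-124-3	LR745790	NA	0.22
mir-1294	LR594714	1.04	NA
mir-1301	LR594715	NA	30.95
mir-1307	LR594716	1.02	543.87
mir-1327	LR745791	1.08	NA
mir-138-1	LR745792	2.20	NA
mir-1468	LR745793	3.87	NA
mir-151b	LR594718	NA	3.50
mir-1839	LR745794	249.11	1.85
mir-1843	LR745796	33.89	51.60
mir-1976	LR745798	1.60	NA
mir-199b	LR594719	230.72	NA
mir-200b	LR745799	0.79	13.71
mir-219b	LR594722	1.33	NA
mir-2355	LR594723	NA	10.11
mir-3074	LR594725	11.20	NA
mir-3074-2	LR745800	11.20	NA
mir-30e	LR745801	3875.85	1023.80
mir-3120	LR594726	4.30	9.52
mir-3155a	LR745803	0.44	7.83
mir-3158	LR594729	NA	14.74
mir-3158-2	LR745804	NA	14.74
mir-3160-1	LR594730	NA	0.72
mir-3160-2	LR745805	NA	0.72
mir-3164	LR745806	0.97	0.56
mir-3174	LR745808	3.28	NA
mir-3191	LR745809	NA	1.24
mir-320b-1	LR745810	NA	119.04
mir-320c-1	LR745811	NA	41.88
mir-320d-1	LR745812	NA	25.86
mir-320d-3	LR745813	NA	25.86
mir-320e	LR745814	NA	2.08
mir-326	LR594733	NA	7.38
mir-3609	LR594734	NA	1.38
mir-3613	LR745815	115.70	NA
mir-3620	LR745816	0.81	NA
mir-3691	LR594736	0.89	NA
mir-371b	LR745817	1.38	NA
mir-378g	LR745818	0.40	NA
mir-3913-1	LR745819	8.91	NA
mir-4485	LR594738	NA	0.38
mir-4659a	LR745820	NA	0.93
mir-4661	LR745821	0.75	NA
mir-4676	LR594739	16.80	NA
mir-4684	LR594740	0.71	0.56
mir-4791	LR594741	0.63	NA
mir-486-1	LR745823	7013.65	332.08
mir-4999	LR745825	1.41	0.26
mir-548ad	LR594743	2.20	NA
mir-548at	LR745827	1.34	NA
mir-548av	LR594747	NA	0.36
mir-548ay	LR594748	3.98	NA
mir-548l	LR745828	NA	1.08
mir-5690	LR594755	4.21	NA
mir-610	LR594756	8.26	NA
mir-641	LR594757	1.06	NA
mir-6501	LR594758	1.74	NA
mir-6503	LR745829	7.58	18.52
mir-6503-2	LR745831	0.17	12.61
mir-6516	LR745833	0.32	NA
mir-655	LR594759	NA	2.35
mir-6731	LR594760	1.20	NA
mir-6735	LR745834	1.14	0.09
mir-6813	LR594761	0.69	NA
mir-6816	LR745836	NA	0.82
mir-6866	LR745837	0.69	NA
mir-7155	LR594762	NA	0.68
mir-744	LR594763	1140.67	1.71
mir-7848	LR594765	NA	18.23
mir-935	LR745838	NA	1.44
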