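21	1199999	1200000	1	61999999	62000000	J001	10	+	+
1	60000000	60000001	8	18000000	18000001	J002	10	-	-
8	18999999	19000000	9	5000000	5000001	J003	10	+	-
9	5599999	5600000	1	70799999	70800000	J004	10	+	+
1	70000000	70000001	34	10000000	10000001	J005	10	-	-
34	10399999	10400000	8	31199999	31200000	J006	10	+	+
8	30000000	30000001	9	22000000	22000001	J007	10	-	-
9	22499999	22500000	34	2299999	2300000	J008	10	+	+
34	2000000	2000001	7	40000000	40000001	J009	10	-	-
7	45499999	45500000	7	1499999	1500000	J010	10	+	+
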