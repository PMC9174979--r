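gene	start_np	end_np	strand	category
RNR1	1	975	+	rRNA
tRNA-Val	983	1051	+	tRNA
RNR2	1052	2641	+	rRNA
tRNA-Leu-UUR	2650	2724	+	tRNA
ND1	2736	3713	+	protein_coding
tRNA-Ile	3722	3792	+	tRNA
tRNA-Gln	3800	3870	-	tRNA
tRNA-Met	3878	3946	+	tRNA
ND2	3980	4996	+	protein_coding
tRNA-Trp	5003	5071	+	tRNA
tRNA-Ala	5079	5147	-	tRNA
tRNA-Asn	5155	5227	-	tRNA
tRNA-Cys	5233	5299	-	tRNA
tRNA-Tyr	5305	5375	-	tRNA
CO1	5385	6935	+	protein_coding
tRNA-Ser-UCN	6940	7012	-	tRNA
tRNA-Asp	7018	7086	+	tRNA
CO2	7096	7779	+	protein_coding
tRNA-Lys	7788	7855	+	tRNA
ATP8	7862	8029	+	protein_coding
ATP6	8020	8703	+	protein_coding
CO3	8706	9489	+	protein_coding
tRNA-Gly	9490	9558	+	tRNA
ND3	9559	9909	+	protein_coding
tRNA-Arg	9912	9980	+	tRNA
ND4L	9982	10278	+	protein_coding
ND4	10272	11649	+	protein_coding
tRNA-His	11650	11719	+	tRNA
tRNA-Ser-AGY	11720	11785	+	tRNA
tRNA-Leu-CUN	11786	11856	+	tRNA
ND5	11857	13674	+	protein_coding
CYB	13696	14753	+	protein_coding
tRNA-Thr	14758	14826	+	tRNA
CR1	14860	16067	+	control_region
tRNA-Pro	16068	16137	-	tRNA
ND6	16145	16663	-	protein_coding
tRNA-Glu	16668	16736	-	tRNA
CR2	16741	18074	+	control_region
tRNA-Phe	18075	18143	+	tRNA
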