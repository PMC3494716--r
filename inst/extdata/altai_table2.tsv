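id	site	period	hvr1_variants	HaeIII_663	HindII_13259	AluI_5176	HaeII_4830	NlaIII_4577	BstOI_13704	AluI_7025	HaeII_9052	HinfI_12308	AluI_15606	reported_hvr1	reported_rflp
AE05.T2	Alag Erdene	Bronze	223, 292, 362	-	+	-								D	D
AE05.T3	Alag Erdene	Bronze	192, 223, 295, 362	-	+	-								D	D
TSA07.T4	Tsengel Khairkhan	Bronze	092, 223, 311, 362			-								D	D
BTG05.T1	Baga Turgen Gol	Iron	223, 319, 362	-	+	-								D	D
BTG05.T2	Baga Turgen Gol	Iron	093, 224, 311, 319	-	+	+					-	+	-	K	K
BTG05.T8.1	Baga Turgen Gol	Iron	129, 256, 270, 304, 399		+							+		U5a1	U
BTG05.T8.2	Baga Turgen Gol	Iron	223, 298, 327		-	+								C	C
BTG05.T8.3	Baga Turgen Gol	Iron	223, 239, 243, 319, 362											D	
BTG06.T3	Baga Turgen Gol	Iron	069, 126					+	-			-		J	J
BTG06.T8	Baga Turgen Gol	Iron	223, 239, 243, 319, 362	-		-								D	D
BTG06.T10A	Baga Turgen Gol	Iron	172, 311	-		+		+		+	+			HV6	HV
BTG06.T10B	Baga Turgen Gol	Iron	223, 274, 311, 362			-								D	D
BTG06.T11A	Baga Turgen Gol	Iron	093, 224, 311, 319				-				-	+	-	K	K
BTG06.T11B	Baga Turgen Gol	Iron	093, 224, 311, 319								-	+	-	K	K
BTG06.T12	Baga Turgen Gol	Iron	192, 256, 270, 304, 399									+		U5a1	U
BTG06.T13	Baga Turgen Gol	Iron	093, 129, 223, 298, 327, 362		-									C	C
TSK07.T1	Tsengel Khairkhan	Iron	093, 223, 242, 278, 290, 311, 319	+		+								A	A
TSK07.T2A	Tsengel Khairkhan	Iron	223, 227, 278, 362			+	+					-		G2a	G
TSK07.T2B	Tsengel Khairkhan	Iron	126, 163, 186, 189, 294									-	+	T1	T
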