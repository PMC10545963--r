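line_id	phenotype	lcyb	clcyb600	m7
PS186	ICY	CC	CC	c2c2
PS187	ICY	CC	CC	c2c2
PS189	ICY	CC	CC	c2c2
PS160	CY	CC	CC	C2C2
PS188	CY	CC	CC	C2C2
PS190	CY	CC	CC	C2C2
2901	CY	CC	CC	C2C2
2902	CY	CC	CC	C2C2
2903	CY	CC	CC	C2C2
2904	CY	CC	CC	C2C2
2906	CY	CC	CC	C2C2
2908	CY	CC	CC	C2c2
2909	CY	CC	CC	C2C2
2911	CY	CC	CC	C2C2
ALDF	CY	CC	CC	C2C2
OTO9491	CY	CC	CC	C2C2
2962	R	cc	cc	C2C2
2964	R	cc	cc	c2c2
2966	R	cc	cc	c2c2
2985	R	cc	cc	C2C2
2987	R	cc	cc	c2c2
2995	R	cc	cc	C2C2
2998	R	cc	cc	c2c2
3005	R	cc	cc	c2c2
DAH	R	cc	cc	c2c2
JB11-3	R	cc	cc	c2c2
JB38-1	R	cc	cc	C2C2
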