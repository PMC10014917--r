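gene	suballele	major	function	chrom	pos	ref	alt	rsid	is_core	is_reference
CYP2C19	*1.001	*1	normal						FALSE	FALSE
CYP2C19	*1.001	*1		10	94842866	A	G	rs3758581	TRUE	FALSE
CYP2C19	*1.002	*1	normal						FALSE	FALSE
CYP2C19	*1.002	*1		10	94842866	A	G	rs3758581	TRUE	FALSE
CYP2C19	*1.002	*1		10	94770001	T	C		FALSE	FALSE
CYP2C19	*1.005	*1	normal						FALSE	FALSE
CYP2C19	*1.005	*1		10	94842866	A	G	rs3758581	TRUE	FALSE
CYP2C19	*1.005	*1		10	94770005	G	A		FALSE	FALSE
CYP2C19	*1.006	*1	normal						FALSE	FALSE
CYP2C19	*1.006	*1		10	94842866	A	G	rs3758581	TRUE	FALSE
CYP2C19	*1.006	*1		10	94770006	C	T		FALSE	FALSE
CYP2C19	*2.001	*2	no_function						FALSE	FALSE
CYP2C19	*2.001	*2		10	94781859	G	A	rs4244285	TRUE	FALSE
CYP2C19	*2.002	*2	no_function						FALSE	FALSE
CYP2C19	*2.002	*2		10	94781859	G	A	rs4244285	TRUE	FALSE
CYP2C19	*2.002	*2		10	94775165	G	C		FALSE	FALSE
CYP2C19	*2.002	*2		10	94771002	A	G		FALSE	FALSE
CYP2C19	*2.010	*2	no_function						FALSE	FALSE
CYP2C19	*2.010	*2		10	94781859	G	A	rs4244285	TRUE	FALSE
CYP2C19	*2.010	*2		10	94775165	G	C		FALSE	FALSE
CYP2C19	*2.010	*2		10	94771010	C	A		FALSE	FALSE
CYP2C19	*2.011	*2	no_function						FALSE	FALSE
CYP2C19	*2.011	*2		10	94781859	G	A	rs4244285	TRUE	FALSE
CYP2C19	*2.011	*2		10	94762608	T	C	rs4986894	FALSE	FALSE
CYP2C19	*2.012	*2	no_function						FALSE	FALSE
CYP2C19	*2.012	*2		10	94781859	G	A	rs4244285	TRUE	FALSE
CYP2C19	*2.012	*2		10	94775165	G	C		FALSE	FALSE
CYP2C19	*2.012	*2		10	94771012	G	T		FALSE	FALSE
CYP2C19	*3.002	*3	no_function						FALSE	FALSE
CYP2C19	*3.002	*3		10	94780653	G	A	rs4986893	TRUE	FALSE
CYP2C19	*3.002	*3		10	94781616	A	G	rs7088784	FALSE	FALSE
CYP2C19	*11.001	*11	normal						FALSE	FALSE
CYP2C19	*11.001	*11		10	94775507	G	A		TRUE	FALSE
CYP2C19	*17.001	*17	increased						FALSE	FALSE
CYP2C19	*17.001	*17		10	94761900	C	T	rs12248560	TRUE	FALSE
CYP2C19	*38.001	*38	normal						FALSE	TRUE
CYP2C19	*38.003	*38	normal						FALSE	FALSE
CYP2C19	*38.003	*38		10	94772038	A	C		FALSE	FALSE
CYP2C19	*38.003	*38		10	94772039	T	G		FALSE	FALSE
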