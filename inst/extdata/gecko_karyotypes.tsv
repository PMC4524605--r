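species	diploid_number	fundamental_number	chromosome	morphology	size_class	sex	sex_system
GHO	38	42	1	submetacentric	macro	none	ZW
GHO	38	42	2	submetacentric	macro	none	ZW
GHO	38	42	3	acrocentric	macro	none	ZW
GHO	38	42	4	acrocentric	macro	Z	ZW
GHO	38	42	5	acrocentric	macro	none	ZW
GHO	38	42	6	subtelocentric	macro	none	ZW
GHO	38	42	7	acrocentric	macro	none	ZW
GHO	38	42	8	acrocentric	macro	none	ZW
GHO	38	42	9	acrocentric	macro	none	ZW
GHO	38	42	10	acrocentric	macro	none	ZW
GHO	38	42	11	acrocentric	macro	none	ZW
GHO	38	42	12	acrocentric	macro	none	ZW
GHO	38	42	13	subtelocentric	macro	none	ZW
GHO	38	42	14	subtelocentric	macro	none	ZW
GHO	38	42	15	subtelocentric	macro	none	ZW
GHO	38	42	16	submetacentric	macro	none	ZW
GHO	38	42	17	subtelocentric	macro	none	ZW
GHO	38	42	18	metacentric	macro	none	ZW
GHO	38	42	19	submetacentric	macro	none	ZW
GHO	38	42	W	subtelocentric	macro	W	ZW
LAG	38		1	acrocentric	macro	none	ZW
LAG	38		2	acrocentric	macro	none	ZW
LAG	38		3	acrocentric	macro	none	ZW
LAG	38		4	acrocentric	macro	none	ZW
LAG	38		5	acrocentric	macro	Z	ZW
LAG	38		6	acrocentric	macro	none	ZW
LAG	38		7	acrocentric	macro	none	ZW
LAG	38		8	acrocentric	macro	none	ZW
LAG	38		9	acrocentric	macro	none	ZW
LAG	38		10	acrocentric	macro	none	ZW
LAG	38		11	acrocentric	macro	none	ZW
LAG	38		12	acrocentric	macro	none	ZW
LAG	38		13	acrocentric	macro	none	ZW
LAG	38		14	acrocentric	macro	none	ZW
LAG	38		15	acrocentric	macro	none	ZW
LAG	38		16	acrocentric	macro	none	ZW
LAG	38		17	acrocentric	macro	none	ZW
LAG	38		18	acrocentric	macro	none	ZW
LAG	38		19	micro	micro	none	ZW
LAG	38		W	micro	micro	W	ZW
VSA	40		1	metacentric	macro	none	ZW
VSA	40		2	submetacentric	macro	none	ZW
VSA	40		3	submetacentric	macro	none	ZW
VSA	40		4	submetacentric	macro	none	ZW
VSA	40		5	submetacentric	macro	none	ZW
VSA	40		6	submetacentric	macro	none	ZW
VSA	40		7	submetacentric	macro	none	ZW
VSA	40		8	submetacentric	macro	none	ZW
VSA	40		M1	micro	micro	none	ZW
VSA	40		M2	micro	micro	none	ZW
VSA	40		M3	micro	micro	none	ZW
VSA	40		M4	micro	micro	none	ZW
VSA	40		M5	micro	micro	none	ZW
VSA	40		M6	micro	micro	none	ZW
VSA	40		M7	micro	micro	none	ZW
VSA	40		M8	micro	micro	none	ZW
VSA	40		M9	micro	micro	none	ZW
VSA	40		M10	micro	micro	none	ZW
VSA	40		M11	micro	micro	none	ZW
VSA	40		M12	micro	micro	none	ZW
LRE	36		1	metacentric	macro	none	unknown
LRE	36		2	submetacentric	macro	none	unknown
LRE	36		3	submetacentric	macro	none	unknown
LRE	36		4	submetacentric	macro	none	unknown
LRE	36		5	submetacentric	macro	none	unknown
LRE	36		6	submetacentric	macro	none	unknown
LRE	36		M1	micro	micro	none	unknown
LRE	36		M2	micro	micro	none	unknown
LRE	36		M3	micro	micro	none	unknown
LRE	36		M4	micro	micro	none	unknown
LRE	36		M5	micro	micro	none	unknown
LRE	36		M6	micro	micro	none	unknown
LRE	36		M7	micro	micro	none	unknown
LRE	36		M8	micro	micro	none	unknown
LRE	36		M9	micro	micro	none	unknown
LRE	36		M10	micro	micro	none	unknown
LRE	36		M11	micro	micro	none	unknown
LRE	36		M12	micro	micro	none	unknown
EQU	36		1	submetacentric	macro	none	ZW
EQU	36		2	submetacentric	macro	none	ZW
EQU	36		3	submetacentric	macro	none	ZW
EQU	36		4	submetacentric	macro	none	ZW
EQU	36		5	submetacentric	macro	none	ZW
EQU	36		6	submetacentric	macro	none	ZW
EQU	36		7	submetacentric	macro	none	ZW
EQU	36		Z	submetacentric	macro	Z	ZW
EQU	36		W	submetacentric	macro	W	ZW
EQU	36		M1	micro	micro	none	ZW
EQU	36		M2	micro	micro	none	ZW
EQU	36		M3	micro	micro	none	ZW
EQU	36		M4	micro	micro	none	ZW
EQU	36		M5	micro	micro	none	ZW
EQU	36		M6	micro	micro	none	ZW
EQU	36		M7	micro	micro	none	ZW
EQU	36		M8	micro	micro	none	ZW
EQU	36		M9	micro	micro	none	ZW
EQU	36		M10	micro	micro	none	ZW
ACA	36		1	metacentric	macro	none	unknown
ACA	36		2	metacentric	macro	none	unknown
ACA	36		3	metacentric	macro	none	unknown
ACA	36		4	metacentric	macro	none	unknown
ACA	36		5	metacentric	macro	none	unknown
ACA	36		6	metacentric	macro	none	unknown
ACA	36		M1	micro	micro	none	unknown
ACA	36		M2	micro	micro	none	unknown
ACA	36		M3	micro	micro	none	unknown
ACA	36		M4	micro	micro	none	unknown
ACA	36		M5	micro	micro	none	unknown
ACA	36		M6	micro	micro	none	unknown
ACA	36		M7	micro	micro	none	unknown
ACA	36		M8	micro	micro	none	unknown
ACA	36		M9	micro	micro	none	unknown
ACA	36		M10	micro	micro	none	unknown
ACA	36		M11	micro	micro	none	unknown
ACA	36		M12	micro	micro	none	unknown
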