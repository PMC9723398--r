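# Illustrative kinase consensus motif library (one motif per line: kinase<TAB>pattern).
# "*" marks the phosphoacceptor, "x" is a wildcard, "[..]" is a residue set.
# Consensus patterns follow widely cited substrate preferences; this is a
# benchmarking default, not a curated substrate database.
PKA	R-R-x-[ST]*
PKC	[ST]*-x-[RK]
CAMK2	R-x-x-[ST]*-[ILVF]
AKT	R-x-R-x-x-[ST]*
CK2	[ST]*-x-x-E
CK1	[DE]-x-x-[ST]*
CDK1	[ST]*-P-x-[RK]
MAPK	P-x-[ST]*-P
GSK3	[ST]*-x-x-x-S
ATM	[ST]*-Q
PLK1	[DE]-x-[ST]*-x-x-[DE]
SRC	[DE]-x-x-Y*
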