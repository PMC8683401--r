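# Bundled PTM site-class patterns (NAME<TAB>PATTERN<TAB>SOURCE).
# Patterns follow the current PROSITE entries for each site class.
CK2_PHOSPHO_SITE	[ST]-X(2)-[DE]	PROSITE PS00006
PKC_PHOSPHO_SITE	[ST]-X-[RK]	PROSITE PS00005
CAMP_PHOSPHO_SITE	[RK](2)-X-[ST]	PROSITE PS00004
TYR_PHOSPHO_SITE	[RK]-X(2,3)-[DE]-X(2,3)-Y	PROSITE PS00007
ASN_GLYCOSYLATION	N-{P}-[ST]-{P}	PROSITE PS00001
MYRISTYL	G-{EDRKHPFYW}-X(2)-[STAGCN]-{P}	PROSITE PS00008
AMIDATION	X-G-[RK]-[RK]	PROSITE PS00009
LEUCINE_ZIPPER	L-X(6)-L-X(6)-L-X(6)-L	PROSITE PS00029
ATP_GTP_A	[AG]-X(4)-G-K-[ST]	PROSITE PS00017
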