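gene	public_cnv	public_snp	exome_cnv	exome_snv	band
ACOXL	no	no	no	sv2c	2q13
ACSM1	no	no	no	2vsc	16p12.3
ANKRD42	no	no	no	sv2c	11q14.1
CNGB3	yes	no	no	yes	8q21.3
CYFIP2	no	no	no	sv2c	5q33.3
CYP19A1	yes	no	no	yes	15q21.2
DDX60	yes	no	no	yes	4q32.3
DNAH3	no	no	no	sv2c	16p12.3
DNHD1	yes	no	no	yes	11p15.4
EMP2	yes	yes	no	no	16p13.13
GIMAP6	no	no	no	2vsc	7q36.1
GOLGA8DP	yes	no	yes	no	15q11.2
HEATR1	yes	no	no	yes	1q43
IFLTD1	no	no	no	3vsc	12p12.1
ILDR1	no	no	no	2vsc	3q13.33
ITGA3	yes	no	no	yes	17q21.33
MSR1	no	no	no	sv2c	8p22
MUC6	no	no	no	2vsc	11p15.5
NPSR1	no	no	no	sv2c	7p14.3
OBSL1	no	no	no	sv2c	2q35
OR8K3	yes	no	no	yes	11q12.1
PPP6R3	yes	no	no	yes	11q13.2
RGS12	no	no	no	2vsc	4p16.3
SDK1	yes	no	no	yes	7p22.2
SMYD3	yes	no	no	yes	1q44
TRIM22	yes	no	no	yes	11p15.4
TRIM48	no	no	sv2c	no	11q11
TRIML2	yes	no	no	yes	4q35.2
UQCRC2	yes	no	no	yes	16p12.2
VWDE	no	no	no	2vsc	7p21.3
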