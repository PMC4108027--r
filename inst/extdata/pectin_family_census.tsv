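family	arabidopsis	physcomitrella	min_ancestral
UDP-Rhamnose synthases	4	6	1
UDP-Glucuronic acid epimerases	5	9	1
Galacturonosyltransferases (GAUTs)	15	8	3
GAUT-like proteins (GATLs)	10	3	1
Galactan galactosyltransferases	3	4	1
RG-II xylosyltransferases	4	1	1
RG-I arabinosyltransferases	2	0	ND
XGA xylosyltransferases	2	0	ND
HG methyltransferases	6	3	2
Pectin methylesterases	66	14	5
Pectin methylesterase inhibitors (PMEIs)	2	0	ND
Polygalacturonases	67	10	5
Polygalacturonase inhibitor proteins (PGIPs)	2	0	ND
Pectate lyase-like proteins	26	7	2
Pectin acetylesterases	11	1	1
Pectin acetyltransferases	4	3	1
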