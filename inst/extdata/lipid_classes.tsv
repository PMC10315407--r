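code	category	chains_per_molecule	name
CE	neutral	1	cholesteryl ester
MAG	neutral	1	monoacylglycerol
DAG	neutral	2	diacylglycerol
TG	neutral	3	triacylglycerol
SM	sphingolipid	1	sphingomyelin
CER	sphingolipid	1	ceramide
DCER	sphingolipid	1	dihydroceramide
HCER	sphingolipid	1	hexosylceramide
LCER	sphingolipid	1	lactosylceramide
PC	phospholipid	2	phosphatidylcholine
LPC	phospholipid	1	lysophosphatidylcholine
PE	phospholipid	2	phosphatidylethanolamine
LPE	phospholipid	1	lysophosphatidylethanolamine
PEO	phospholipid	2	phosphatidylethanolamine ether
PEP	phospholipid	2	phosphatidylethanolamine plasmalogen
PI	phospholipid	2	phosphatidylinositol
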