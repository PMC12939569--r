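sequence	lr	svm	mlp	cdocker_energy	cdocker_interaction
QICVCDS	high activity	high activity	high activity	125.954	118.496
DVWK	high activity	low & non-activity	low & non-activity	117.488	106.022
IIEY	high activity	high activity	high activity	105.96	105.308
APMDVG	high activity	low & non-activity	low & non-activity	100.198	104.216
VIEY	high activity	high activity	high activity	107.679	101.273
CR	high activity	high activity	high activity	51.7598	98.9681
DCPN	high activity	high activity	high activity	84.6444	95.1822
AVIL	low & non-activity	high activity	low & non-activity	97.2242	91.1243
NWY	high activity	high activity	high activity	94.1639	90.5661
CIMD	high activity	high activity	high activity	87.2086	87.2189
CDF	high activity	high activity	high activity	89.6301	85.0382
VWF	high activity	high activity	high activity	84.9517	82.9004
DPG	high activity	low & non-activity	low & non-activity	82.186	80.9088
CNL	high activity	high activity	high activity	88.73	80.173
IPT	high activity	high activity	high activity	60.7788	78.4556
CVY	high activity	high activity	high activity	83.7145	77.1025
ANH	low & non-activity	high activity	high activity	90.0769	76.6198
WY	high activity	high activity	high activity	74.7127	75.5368
CIH	high activity	high activity	high activity	76.0867	74.1174
APL	low & non-activity	high activity	high activity	62.8983	72.4292
APD	high activity	low & non-activity	high activity	51.6015	72.3056
PPF	low & non-activity	high activity	high activity	47.0456	71.9965
VL	high activity	high activity	high activity	70.8135	66.6751
VY	high activity	high activity	high activity	71.7841	66.6652
CH	high activity	high activity	high activity	70.8717	66.3302
CS	high activity	low & non-activity	high activity	65.5785	60.116
MP	high activity	high activity	high activity	38.9863	55.042
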