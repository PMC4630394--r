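constituent	center_cm1	functional_group	literature_ref
extractives	1730	C=O stretching, ester carbonyl	wood extractives IR
extractives	1633	olefinic C=C stretching	wood extractives IR
extractives	1600	C=C stretching / aromatic ring deformation	wood extractives IR
extractives	1510	benzene ring deformation vibration	wood extractives IR
extractives	1271	C-O stretch with in-plane C-OH bending, carboxylic acids	wood extractives IR
lignin	1735	C=O stretching	lignin IR
lignin	1658	conjugated C=O stretching	lignin IR
lignin	1510	aromatic skeletal vibration	lignin IR
lignin	1425	aromatic skeletal vibration	lignin IR
lignin	1375	phenolic OH and aliphatic C-H in methyl groups	lignin IR
lignin	1328	aromatic skeletal vibration	lignin IR
lignin	1269	G ring with C=O stretching	lignin IR
lignin	1220	C-C, C-O and C=O stretching	lignin IR
lignin	1140	C-H in-plane deformation of G ring; secondary alcohols; C=O stretch	lignin IR
lignin	1116	aromatic C-H deformation in S ring	lignin IR
lignin	1033	aromatic C-H in-plane deformation; C-O of primary alcohols; C=O stretch	lignin IR
lignin	835	C-H out-of-plane deformation, positions 2 and 6 of S ring	lignin IR
cellulose	1440	O-H in-plane bending	cellulose IR
cellulose	1380	C-H bending	cellulose IR
cellulose	1310	CH2 wagging	cellulose IR
cellulose	1280	C-H bending	cellulose IR
cellulose	1220	O-H in-plane bending	cellulose IR
cellulose	1160	C-O-C asymmetric stretching	cellulose IR
cellulose	1047	C-O stretching, range endpoint	cellulose IR
cellulose	1004	C-O stretching, range endpoint	cellulose IR
hemicellulose	1639	absorbed water / conjugated carbonyl (acetylated xylan)	hemicellulose IR
hemicellulose	1453	CH2 symmetric bending	hemicellulose IR
hemicellulose	1426	CH and OH bending	hemicellulose IR
hemicellulose	1338	CH wagging	hemicellulose IR
hemicellulose	1051	glycosidic C-O-C stretching, range endpoint	hemicellulose IR
hemicellulose	1008	glycosidic C-O-C stretching, range endpoint	hemicellulose IR
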