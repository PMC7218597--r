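#ui	name	tree_numbers
D001001	Infections	C01
D001002	Virus Diseases	C02
D001003	Parasitic Diseases	C03
D001004	Neoplasms	C04
D001005	Musculoskeletal Diseases	C05
D001006	Digestive System Diseases	C06
D001007	Stomatognathic Diseases	C07
D001008	Respiratory Tract Diseases	C08
D001009	Otorhinolaryngologic Diseases	C09
D001010	Nervous System Diseases	C10
D001011	Eye Diseases	C11
D001012	Male Urogenital Diseases	C12
D001013	Female Urogenital Diseases and Pregnancy Complications	C13
D001014	Cardiovascular Diseases	C14
D001015	Hemic and Lymphatic Diseases	C15
D001016	Congenital, Hereditary, and Neonatal Diseases and Abnormalities	C16
D001017	Skin and Connective Tissue Diseases	C17
D001018	Nutritional and Metabolic Diseases	C18
D001019	Endocrine System Diseases	C19
D001020	Immune System Diseases	C20
D001021	Disorders of Environmental Origin	C21
D001022	Animal Diseases	C22
D001023	Pathological Conditions, Signs and Symptoms	C23
D001024	Occupational Diseases	C24
D001025	Chemically-Induced Disorders	C25
D001026	Wounds and Injuries	C26
D002001	Antineoplastic Agents	D27.505.954.248
D002002	Anti-Inflammatory Agents	D27.505.954.158
D002003	Lipid Regulating Agents	D27.505.954.502
D002004	Antineoplastic Agents, Hormonal	D27.505.954.248.500
D002005	Immunologic Factors	D27.505.696.477
D000069287	Capecitabine	D03.383.129.154
D009944	Oxaliplatin	D02.455.426.559
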