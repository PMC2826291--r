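Sudan
Central Equatoria	Sudan
Yei County	Central Equatoria
Pakistan
Punjab	Pakistan
Lahore	Punjab
Sindh	Pakistan
Karachi	Sindh
Thailand
Bangkok	Thailand
Khon Kaen	Thailand
Vietnam
Lai Chau Province	Vietnam
Can Tho	Vietnam
Japan
Tokyo	Japan
Indonesia
Jakarta	Indonesia
Canada
Ontario	Canada
Toronto	Ontario
India
West Bengal	India
Murshidabad	West Bengal
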