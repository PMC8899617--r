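code,name,open_or_forest
1,tropical evergreen forest,forest
2,tropical semi-deciduous forest,forest
3,tropical deciduous forest/woodland,forest
4,warm-temperate mixed forest,forest
5,temperate conifer forest,forest
6,temperate sclerophyll woodland,forest
7,open conifer woodland,forest
8,tropical savannah,open
9,tropical xerophytic shrubland,open
10,temperate xerophytic shrubland,open
11,tropical grassland,open
12,temperate grassland,open
13,steppe,open
14,semi-desert,open
15,desert,open
16,barren or sparsely vegetated,open
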