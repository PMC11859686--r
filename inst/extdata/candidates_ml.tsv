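plant_name	weight
Cyperus rotundus	0.03109277
Piper longum	0.0261781
Aconitum ferox	0.02305289
Sida cordifolia	0.01956573
Piper nigrum	0.01927294
Zingiber officinale	0.01859687
Myristica fragrans	0.01832107
Plumbago zeylanica	0.01659803
Acacia leucophloea	0.01593949
Terminalia chebula	0.01574221
Trichosanthes dioica	0.01567844
Cinnamomum zeylanicum	0.01544429
Bambusa bambos	0.01483098
Elettaria cardamomum	0.0143906
Inula racemosa	0.0140497
Curcuma longa	0.01371762
Piper chaba	0.0136643
Punica granatum	0.01346506
Carum curvi	0.01325254
Femia foetida	0.01210255
Tenninalia chebula	0.01149938
Aconitum heterophyllum	0.0111556
Emblica officinalis	0.01114156
Adhatoda vasica	0.01106956
Fagonia cretica	0.01092521
Berberies aristata	0.01090131
Berberis aristata	0.0107864
Bharangi—Clerodendrum	0.01015191
Syzygium aromaticum	0.01012223
Operculina turpethum	0.01011386
Terminalia bellcrica	0.01009841
Hollerrhena antidysentrica	0.01003895
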