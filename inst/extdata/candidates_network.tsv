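plant_name	support
Zingiber officinale	6
Cyperus rotundus	5
Piper longum	5
Nigella sativa	4
Rhus succedanea	4
Tinospora cordifolia	4
Terminalia chebula	4
Bharangi—Clerodendrum	3
Carum curvi	3
Cedrus deodara	3
Coriandrum sativum	3
Emblica officinalis	3
Myrica nagi/Myrica sapida	3
Piper nigrum	3
Saussurea hypoleuca	3
Fagonia cretica	3
Picrorhiza kurroa	3
Cinnamomum tamala	2
Cinnamomum zeylanicum	2
Croton polyandrum	2
Elettaria cardamomum	2
Glycyrrhiza glabra	2
Myristica fragrans	2
Piper chaba	2
Plumbago zeylanica	2
Syzygium aromaticum	2
Trachyspermum ammi carum copticum	2
Trianthema portulacastrum	2
Tribulus terrestris	2
Uraria lagopoides	2
Aegle marmelos	2
Solanum indicum	2
Aconitum heterophyllum	2
Cissampelos pareira	2
Azadirachta indica	2
Curcuma longa	2
Trichosanthes dioica	2
Inula racemosa	2
Nigella sativa	2
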