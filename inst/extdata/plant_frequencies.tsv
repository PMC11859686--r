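rank	plant_name	frequency
1	Piper longum	102
2	Zingiber officinale	93
3	Emblica officinalis	74
4	Piper nigrum	69
5	Terminalia chebula	56
6	Myristica fragrans	54
7	Cyperus rotundus	53
8	Tenninalia chebula	50
9	Terminalia bellcrica	37
10	Piper chaba	36
11	Plumbago zeylanica	34
12	Syzygium aromaticum	32
13	Coriandrum sativum	32
14	Cinnamomum zeylanicum	30
15	Elettaria cardamomum	30
16	Saussurea hypoleuca	30
17	Aconitum ferox	29
18	Aloe barbadensis	29
19	Tinospora cordifolia	29
20	Nigella sativa	29
21	Carum curvi	28
22	Cinnamomum tamala	28
23	Glycyrrhiza glabra	27
24	Pterocarpus santalinus	27
25	Berberis aristata	26
26	Embelia ribes	25
27	Cedrus deodara	24
28	Acorus calamus	24
29	Tribulus terresrris	23
30	Curcuma longa	23
31	Aegle marmelos	22
32	Trachyspermum ammi	22
33	Sida cordifolia	22
34	Aconitum heterophyllum	21
35	Operculina turpethum	21
36	Mesua ferrea	20
37	Rhus succedanea	19
38	Curcuma zedoaria	19
39	Hollerrhena antidysenterica	18
40	Picrorhiza kurroa	18
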