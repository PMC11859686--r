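variant,canonical
Tenninalia chebula,Terminalia chebula
Carum curvi,Carum carvi
Berberies aristata,Berberis aristata
Hollerrhena antidysentrica,Hollerrhena antidysenterica
Tribulus terresrris,Tribulus terrestris
Bharangi,Bharangi—Clerodendrum
Trachyspermum ammi carum copticum,Trachyspermum ammi
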