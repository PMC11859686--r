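plant_name
Piper longum
Piper nigrum
Zingiber officinale
Myristica fragrans
Plumbago zeylanica
Trichosanthes dioica
Cinnamomum zeylanicum
Elettaria cardamomum
Inula racemosa
Curcuma longa
Piper chaba
Carum carvi
Terminalia chebula
Aconitum heterophyllum
Emblica officinalis
Fagonia cretica
Bharangi
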