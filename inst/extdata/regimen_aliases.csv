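alias,canonical
CAPECITABINE,5FU
5-FU,5FU
FU5,5FU
DE GRAMONT,5FU
XELOX,FOLFOX
CAPOX,FOLFOX
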