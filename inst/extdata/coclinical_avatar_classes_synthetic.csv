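zpdx_id,treatment,recist
P01,FOLFOX,PR
P02,FOLFIRI,PR
P03,FOLFOXIRI,PR
P04,FOLFOX,PR
C038,5FU,CR
P06,FOLFIRI,SD
P07,FOLFOXIRI,SD
P08,FOLFOX,PR
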