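# Synthetic demo calcium-signaling gene set for examples and fixtures.
# A small hand-picked list of calcium-handling genes; not a licensed GO/KEGG
# term export. Supply your own annotation file for real analyses.
RYR1
RYR3
CACNA1S
CAMK4
GRM5
ATP2B3
GRIN1
CAMK2B
ATP2A1
SLN
CASQ2
ITPR1
CACNA1H
TRPC6
CALM1
PVALB
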