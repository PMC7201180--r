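# Collapse of the 15-state chromatin model into 5 groups.
# Edit freely; assignStates() accepts any label -> group mapping.
promoter:
  - 1_TssA
  - 2_TssAFlnk
enhancer:
  - 6_EnhG
  - 7_Enh
transcribed:
  - 3_TxFlnk
  - 4_Tx
  - 5_TxWk
bivalent:
  - 10_TssBiv
  - 11_BivFlnk
  - 12_EnhBiv
repressed:
  - 8_ZNF/Rpts
  - 9_Het
  - 13_ReprPC
  - 14_ReprPCWk
  - 15_Quies
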