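# Final indicator weights of the seven-indicator PSR ecosystem health index.
# Pressure dimension (0.3): PD, LFI. State dimension (0.7): NDVI, LDI, APAI,
# ESV, ER. Used when no expert elicitation input is supplied.
weights:
  PD: 0.20
  LFI: 0.10
  NDVI: 0.24
  LDI: 0.09
  APAI: 0.05
  ESV: 0.22
  ER: 0.10
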