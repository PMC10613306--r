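# Absolute HeLa reference concentrations (uM) used to convert HeLa-relative
# expression to molar concentrations for the caspase-execution surrogate.
# These are documented placeholder defaults of plausible magnitude, NOT
# measured values; override this file with your own reference measurements.
concentrations_uM:
  APAF1: 0.4
  BAK:   0.2
  BAX:   0.3
  BCLXL: 0.2
  BCL2:  0.1
  BID:   0.2
  BIM:   0.05
  MCL1:  0.05
  NOXA:  0.05
  CASP3: 0.2
  CASP9: 0.02
  PUMA:  0.05
  SMAC:  0.4
  XIAP:  0.1
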