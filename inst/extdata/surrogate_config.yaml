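# Surrogate model configuration (version 1)
#
# All values below are documented placeholder defaults of plausible
# physiological magnitude, chosen once for the packaged surrogates; they are
# intended to be overridden by users with measured or literature values for
# their own system. Units: concentrations/Kd in uM, first-order rates in
# min^-1, second-order rates in uM^-1 min^-1.

# Protein-protein dissociation constants: each ligand (rows) vs each
# anti-apoptotic protein (columns). ACT is the generic promiscuous
# stress-induced BH3-only activator scanned by the stress-dose search.
kd_uM:
  BAX:    {BCL2: 0.002, BCLXL: 0.002, MCL1: 0.02}
  BAK:    {BCL2: 0.02,  BCLXL: 0.002, MCL1: 0.002}
  ACT:    {BCL2: 0.001, BCLXL: 0.001, MCL1: 0.001}

# BH3-mimetic dissociation constants vs each anti-apoptotic protein.
# Magnitudes follow the published sub-nanomolar selectivity of each agent
# for its canonical target (ABT-199 -> BCL-2, WEHI-539 -> BCL-XL,
# S63845 -> MCL-1); .inf marks no appreciable binding.
mimetic_kd_uM:
  ABT199:  {BCL2: 0.00001, BCLXL: .inf,   MCL1: .inf}
  WEHI539: {BCL2: .inf,    BCLXL: 0.0011, MCL1: .inf}
  S63845:  {BCL2: .inf,    BCLXL: .inf,   MCL1: 0.0002}

# Fraction of the total BAX+BAK pool that must be free for MOMP.
momp_threshold: 0.1

solver:
  tolerance: 1.0e-8        # uM, equilibrium fixed-point residual
  max_iter: 10000
  eta_upper_uM: 1000       # bisection upper bound for the stress dose
  eta_tolerance_uM: 1.0e-4 # bisection width at termination

# Reduced caspase-execution model rate constants.
caspase_rates:
  k_apop: 20            # apoptosome assembly, uM^-1 min^-1
  k_c3act: 50           # caspase-3 activation by apoptosome, uM^-1 min^-1
  kon_xiap_c3: 100      # XIAP binding active caspase 3, uM^-1 min^-1
  koff_xiap_c3: 1       # min^-1  (Kd 10 nM)
  kon_smac_xiap: 50     # SMAC binding XIAP, uM^-1 min^-1
  koff_smac_xiap: 0.1   # min^-1  (Kd 2 nM)
  k_cleave: 1           # substrate cleavage by active caspase 3, uM^-1 min^-1
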