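# Editable coefficient tables for molecular-weight estimation.
# Version 1. All values may be overridden by passing a user YAML file with
# the same structure to sas_coefficients().

vc:
  # Volume-of-correlation power law MW = (QR / c)^k, QR = Vc^2 / Rg.
  # Constants as published for the volume-of-correlation estimator
  # (protein and RNA calibrations).
  protein:
    c: 0.1231
    k: 1.0
  nucleic:
    c: 0.00934
    k: 0.808

mow:
  # Apparent-Porod-volume method: MW = V' * corr(smax) / density_divisor.
  # density_divisor: cubic angstroms of excluded volume per dalton for an
  # average protein (1/0.83 = 1.2048, protein mass density route).
  # correction: polynomial in smax (A^-1), corr = c0 + c1*smax + c2*smax^2,
  # compensating the overestimation of V' caused by truncating the
  # invariant. These defaults were calibrated on synthetic uniform-sphere
  # curves spanning 20-60 A radius (see the package vignette); replace with
  # method-specific published values if required.
  density_divisor: 1.2048
  correction: [0.6631, 1.1428, -1.1981]

# One water molecule added to the residue-mass sum.
water_mass: 18.0153

residues:
  # Average residue masses (Da) and partial specific volumes (cm^3/g),
  # consensus literature values for the 20 standard amino acids.
  mass:
    "A": 71.0788
    "R": 156.1875
    "N": 114.1038
    "D": 115.0886
    "C": 103.1388
    "E": 129.1155
    "Q": 128.1307
    "G": 57.0519
    "H": 137.1411
    "I": 113.1594
    "L": 113.1594
    "K": 128.1741
    "M": 131.1926
    "F": 147.1766
    "P": 97.1167
    "S": 87.0782
    "T": 101.1051
    "W": 186.2132
    "Y": 163.1760
    "V": 99.1326
  psv:
    "A": 0.74
    "R": 0.70
    "N": 0.62
    "D": 0.60
    "C": 0.63
    "E": 0.66
    "Q": 0.67
    "G": 0.64
    "H": 0.67
    "I": 0.90
    "L": 0.90
    "K": 0.82
    "M": 0.75
    "F": 0.77
    "P": 0.76
    "S": 0.63
    "T": 0.70
    "W": 0.74
    "Y": 0.71
    "V": 0.86
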