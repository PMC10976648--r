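# Triple-dipole (Axilrod-Teller) coefficient table -- schema example.
#
# Keys are the three element symbols of the triple, sorted alphabetically and
# joined with dashes; values are V_ABC in kJ mol^-1 Angstrom^9 (positive for
# noble gases, invariant under permutation of the triple).
#
# The numbers below are SYNTHETIC placeholders for the demonstration elements
# of synthetic_elements(); supply literature coefficients for real elements.
As-As-As: 520.0
As-As-Ks: 780.0
As-Ks-Ks: 1170.0
Ks-Ks-Ks: 1760.0
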