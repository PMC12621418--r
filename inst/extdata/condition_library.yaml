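provenance: >
  Canonical five-condition library for soil-microbiome scope simulations.
  Compound identities not given by name in the published summary table are
  represented by placeholder ids flagged `placeholder: true`; substitute the
  exact identifiers from the detailed supplementary listing when available.
conditions:
  - name: basal_medium
    members:
      # inorganic carbon
      - CARBON-DIOXIDE
      - HCO3
      # inorganic nitrogen
      - N2
      - AMMONIUM
      - NITRATE
      - NITRITE
      # inorganic sulfur
      - HS
      - SO3
      - S2O3
      - SULFATE
      # other inorganic chemicals
      - WATER
      - OXYGEN-MOLECULE
      - H2
      - PROTON
      - HYDROGEN-PEROXIDE
      - Pi
      - CL-
      - ARSENATE
      - {id: BASAL-INORGANIC-09, placeholder: true}
      # metal ions
      - MG+2
      - FE+2
      - NI+2
      - CO+2
      - CU+2
      - MOLYBDATE
      # coenzymes and cofactors
      - NAD
      - FAD
      - CO-A
      - THIAMINE
      - {id: BASAL-COENZYME-05, placeholder: true}
      - {id: BASAL-COENZYME-06, placeholder: true}
      - {id: BASAL-COENZYME-07, placeholder: true}
      - {id: BASAL-COENZYME-08, placeholder: true}
      - {id: BASAL-COENZYME-09, placeholder: true}
      - {id: BASAL-COENZYME-10, placeholder: true}
      - {id: BASAL-COENZYME-11, placeholder: true}
      - {id: BASAL-COENZYME-12, placeholder: true}
      - {id: BASAL-COENZYME-13, placeholder: true}
      - {id: BASAL-COENZYME-14, placeholder: true}
      - {id: BASAL-COENZYME-15, placeholder: true}
      - {id: BASAL-COENZYME-16, placeholder: true}
      - {id: BASAL-COENZYME-17, placeholder: true}
      - {id: BASAL-COENZYME-18, placeholder: true}
  - name: simple_sugars
    parent: basal_medium
    additions:
      - GLC
      - MALTOSE
      - GALACTOSE
      - L-ARABINOSE
      - SORBITOL
      - GLYCEROL
      - {id: SIMPLE-SUGAR-07, placeholder: true}
  - name: complex_sugars
    parent: basal_medium
    additions:
      - TREHALOSE
      - SUCROSE
      - RHAMNOSE
      - MANNITOL
      - XYLITOL
      - LINOLEIC_ACID
      - SPERMIDINE
      - COUMARATE
      - CHORISMATE
      - {id: COMPLEX-SUGAR-10, placeholder: true}
      - {id: COMPLEX-SUGAR-11, placeholder: true}
      - {id: COMPLEX-SUGAR-12, placeholder: true}
      - {id: COMPLEX-SUGAR-13, placeholder: true}
      - {id: COMPLEX-SUGAR-14, placeholder: true}
      - {id: COMPLEX-SUGAR-15, placeholder: true}
      - {id: COMPLEX-SUGAR-16, placeholder: true}
      - {id: COMPLEX-SUGAR-17, placeholder: true}
      - {id: COMPLEX-SUGAR-18, placeholder: true}
      - {id: COMPLEX-SUGAR-19, placeholder: true}
      - {id: COMPLEX-SUGAR-20, placeholder: true}
      - {id: COMPLEX-SUGAR-21, placeholder: true}
  - name: non_sulfured_amino_acids
    parent: basal_medium
    additions:
      - SER
      - PRO
      - VAL
      - THR
      - ILE
      - LEU
      - GLN
      - LYS
      - HIS
      - PHE
      - ARG
      - TYR
      - GLY
      - L-ALPHA-ALANINE
      - L-ASPARTATE
      - ASN
      - GLT
      - TRP
  - name: all_amino_acids
    parent: non_sulfured_amino_acids
    additions:
      - CYS
      - MET
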