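# ACMG secondary-findings v2.0 panel: 59 genes and disease categories.
# Coding intervals live in the companion BED (synthetic placeholder coordinates).
intervals_bed: acmg59_intervals_synthetic.bed
genes:
  - symbol: ACTA2
    category: cardiovascular
  - symbol: ACTC1
    category: cardiovascular
  - symbol: APC
    category: cancers
  - symbol: APOB
    category: familial_hypercholesteremia
  - symbol: ATP7B
    category: others
  - symbol: BMPR1A
    category: cancers
  - symbol: BRCA1
    category: cancers
  - symbol: BRCA2
    category: cancers
  - symbol: CACNA1S
    category: malignant_hyperthermia
  - symbol: COL3A1
    category: cardiovascular
  - symbol: DSC2
    category: cardiovascular
  - symbol: DSG2
    category: cardiovascular
  - symbol: DSP
    category: cardiovascular
  - symbol: FBN1
    category: cardiovascular
  - symbol: GLA
    category: others
  - symbol: KCNH2
    category: cardiovascular
  - symbol: KCNQ1
    category: cardiovascular
  - symbol: LDLR
    category: familial_hypercholesteremia
  - symbol: LMNA
    category: cardiovascular
  - symbol: MEN1
    category: cancers
  - symbol: MLH1
    category: cancers
  - symbol: MSH2
    category: cancers
  - symbol: MSH6
    category: cancers
  - symbol: MUTYH
    category: cancers
  - symbol: MYBPC3
    category: cardiovascular
  - symbol: MYH11
    category: cardiovascular
  - symbol: MYH7
    category: cardiovascular
  - symbol: MYL2
    category: cardiovascular
  - symbol: MYL3
    category: cardiovascular
  - symbol: NF2
    category: cancers
  - symbol: OTC
    category: others
  - symbol: PCSK9
    category: familial_hypercholesteremia
  - symbol: PKP2
    category: cardiovascular
  - symbol: PMS2
    category: cancers
  - symbol: PRKAG2
    category: cardiovascular
  - symbol: PTEN
    category: cancers
  - symbol: RB1
    category: cancers
  - symbol: RET
    category: cancers
  - symbol: RYR1
    category: malignant_hyperthermia
  - symbol: RYR2
    category: cardiovascular
  - symbol: SCN5A
    category: cardiovascular
  - symbol: SDHAF2
    category: cancers
  - symbol: SDHB
    category: cancers
  - symbol: SDHC
    category: cancers
  - symbol: SDHD
    category: cancers
  - symbol: SMAD3
    category: cardiovascular
  - symbol: SMAD4
    category: cancers
  - symbol: STK11
    category: cancers
  - symbol: TGFBR1
    category: cardiovascular
  - symbol: TGFBR2
    category: cardiovascular
  - symbol: TMEM43
    category: cardiovascular
  - symbol: TNNI3
    category: cardiovascular
  - symbol: TNNT2
    category: cardiovascular
  - symbol: TP53
    category: cancers
  - symbol: TPM1
    category: cardiovascular
  - symbol: TSC1
    category: cancers
  - symbol: TSC2
    category: cancers
  - symbol: VHL
    category: cancers
  - symbol: WT1
    category: cancers
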