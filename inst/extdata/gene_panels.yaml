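# Dementia gene panels. Panels must be pairwise disjoint.
# AD_GWAS: 17 genes appear in the cohort results tables; the remaining 17
# (marked supplement_sourced) complete the 34-gene susceptibility panel and
# may be overridden by the user.
AD_CAUSATIVE:
  genes: [APP, PSEN1, PSEN2]
AD_RISK:
  genes: [TREM2, ABCA7, SORL1]
OTHER_DEMENTIA:
  genes: [CCNF, CHCHD10, CSF1R, DCTN1, FIG4, FUS, MAPT, NOTCH3, OPTN,
          SQSTM1, TYROBP, UBQLN2]
AD_GWAS:
  genes: [ADAM10, BIN1, CLU, CR1, ELAVL1, EP300, EPHA1, FERMT2, INPP5D,
          MARK2, MARK4, PICALM, PLCG2, PTK2B, RIN3, TOMM40, ZCWPW1,
          # supplement_sourced, user-overridable:
          ABI3, ACE, ADAMTS1, APH1B, CASS4, CD2AP, CD33, CELF1, ECHDC3,
          IQCK, MEF2C, MS4A4A, MS4A6A, NME8, SLC24A4, SPI1, WWOX]
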