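# Curated SLiM catalog for SYDE1/SYDE2 interactor prediction.
#
# Each class carries the published consensus text verbatim (transliterated
# to ASCII: "phi" = hydrophobic, "pi" = polar), a machine pattern in the
# bounded dialect of compile_motif_pattern(), the printed probability
# score kept as metadata (never recomputed), and its printed instance(s)
# with 1-based inclusive coordinates.
#
# Notes on transcription:
#   * The DOC_Cyclin_RxL instance is printed with end coordinate 175, but
#     the 11-residue peptide starting at 166 ends at 176; `end` stores the
#     length-consistent value and `printed_end` the published one.
#   * `whitelisted: true` marks classes exempt from the probability
#     threshold during candidate selection (modification-site classes and
#     LIG_SH3_3, which are selected on disorder propensity and annotated
#     phosphosites rather than on the motif probability).
version: 1
classes:
- motif_id: LIG_LIR_Gen1
  elm_class: LIG_LIR_Gen1
  interactor: ATG8 (GABARAP)
  consensus_text: "W/F/I-x-x-phi (phi: L,I,F), acidic/phospho-residue upstream"
  pattern: "[EDST][WFYI]..[LIVF]"
  elm_score_printed: 3.60e-03
  pathway: Autophagic pathway
  kind: ligand-site
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 9, end: 13, peptide: TFSRL}
- motif_id: LIG_SH3_3_CIN85
  elm_class: LIG_SH3_3
  interactor: Ruk/CIN85
  consensus_text: "PxxxPR-related SH3 binding, class-independent x-x-x-P/V-x-x-P"
  pattern: "...[PV]..P"
  elm_score_printed: 1.32e-02
  pathway: Synaptic endocytosis
  kind: ligand-site
  whitelisted: true
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 207, end: 213, peptide: DSSVGGP}
  - {protein_id: SYDE1, start: 233, end: 239, peptide: GDSPERP}
  - {protein_id: SYDE1, start: 641, end: 647, peptide: PEVVTRP}
- motif_id: LIG_14_3_3
  elm_class: LIG_14-3-3
  interactor: YWHAZ
  consensus_text: "Arg-containing phospho-motif (14-3-3 binding)"
  pattern: "R..[ST][^P][^P]"
  elm_score_printed: 4.48e-03
  pathway: Neuronal differentiation
  kind: ligand-site
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 177, end: 183, peptide: RRRLSLR}
- motif_id: DOC_Cyclin_RxL
  elm_class: DOC_Cyclin_RxL
  interactor: Cyclin B/CDK1
  consensus_text: "S/T-X-(X)-R/K consensus; RxL docking core"
  pattern: "[RK].L.{0,1}[FYLIVMP]"
  elm_score_printed: 4.21e-03
  pathway: Neuronal differentiation
  kind: docking-site
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 166, end: 176, peptide: RLSIKMKKLPE, printed_end: 175}
- motif_id: DOC_MAPK
  elm_class: DOC_MAPK
  interactor: p38 alpha/beta
  consensus_text: "Classical MAPK D motif: basic pair, 2-4 spacer, phi-x-phi"
  pattern: "[KR][KR].{2,4}[ILVM].[ILVF]"
  elm_score_printed: 4.32e-03
  pathway: Neuronal homeostasis
  kind: docking-site
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 617, end: 626, peptide: RPKRQPPLHL}
- motif_id: MOD_CK1_1
  elm_class: MOD_CK1_1
  interactor: Casein kinase I gamma
  consensus_text: "S-x-x-S/T casein kinase 1 phosphosite"
  pattern: "S..[ST]"
  elm_score_printed: 1.70e-02
  pathway: Endocytosis of synaptic vesicles
  kind: modification-site
  whitelisted: true
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 645, end: 651, peptide: SPPSNRY}
- motif_id: MOD_CK2_1
  elm_class: MOD_CK2_1
  interactor: Casein kinase II
  consensus_text: "pS/pT-D/E-X-D/E casein kinase 2 phosphosite"
  pattern: "[ST]..E"
  elm_score_printed: 1.46e-02
  pathway: Dendritic spine formation
  kind: modification-site
  whitelisted: true
  syde: SYDE1
  instances:
  - {protein_id: SYDE1, start: 678, end: 686, peptide: VTGSDSEDE}
- motif_id: LIG_WW3
  elm_class: LIG_WW3
  interactor: Pin1
  consensus_text: "S/T-P motif (Pin1 WW recognition)"
  pattern: "[ST]P"
  elm_score_printed: 5.67e-04
  pathway: Regulation of NMDA receptor
  kind: ligand-site
  syde: SYDE2
  instances:
  - {protein_id: SYDE2, start: 60, end: 64, peptide: SPPRS}
- motif_id: DOC_PP4
  elm_class: DOC_PP4
  interactor: Smek1
  consensus_text: "FxxP docking motif (PP4 regulatory subunit)"
  pattern: "F..P"
  elm_score_printed: 1.37e-03
  pathway: Neuronal differentiation
  kind: docking-site
  syde: SYDE2
  instances:
  - {protein_id: SYDE2, start: 158, end: 161, peptide: FRDP}
- motif_id: LIG_SH2_Grb2
  elm_class: LIG_SH2_Grb2
  interactor: Grb2
  consensus_text: "pY-x-N Grb2 SH2 binding motif"
  pattern: "Y.N"
  elm_score_printed: 3.18e-04
  pathway: Cerebral cortical development
  kind: ligand-site
  syde: SYDE2
  instances:
  - {protein_id: SYDE2, start: 551, end: 554, peptide: YINS}
- motif_id: DEG_SCF_FBW7
  elm_class: DEG_SCF_FBW7
  interactor: Fbw7
  consensus_text: "phi-X-phi-phi-phi-T-P-P-x-S phospho-degron; TPxxS core"
  pattern: "TP..[ST]"
  elm_score_printed: 7.14e-04
  pathway: Neuronal differentiation
  kind: degron
  syde: SYDE2
  instances:
  - {protein_id: SYDE2, start: 552, end: 562, peptide: INSPDNTPSLS}
- motif_id: DOC_PP2B_LxvP1
  elm_class: DOC_PP2B_LxvP1
  interactor: Calcineurin
  consensus_text: "pi-phi-LxVP calcineurin docking motif"
  pattern: "[STNQHR][FWYLIVM]L.[PV]P"
  elm_score_printed: 2.30e-03
  pathway: Ca2+-dependent synaptic plasticity
  kind: docking-site
  syde: SYDE2
  instances:
  - {protein_id: SYDE2, start: 179, end: 184, peptide: SFLRPP}
- motif_id: LIG_SH3_3_Crk
  elm_class: LIG_SH3_3
  interactor: "Crk, Src"
  consensus_text: "Noncanonical class I RxxPxxP SH3 binding motif"
  pattern: "...[PV]..P"
  elm_score_printed: 1.32e-02
  pathway: Kinase signaling
  kind: ligand-site
  whitelisted: true
  syde: SYDE2
  instances:
  - {protein_id: SYDE2, start: 56, end: 62, peptide: RQQVSPP}
- motif_id: LIG_SH2_Crk_Nck
  elm_class: LIG_SH2_Crk/Nck
  interactor: Crk
  consensus_text: "pY-x-P-x-P Crk/Nck SH2 binding motif"
  pattern: "Y.P.P"
  elm_score_printed: 1.52e-03
  pathway: Conserved phospho-dependent binding
  kind: ligand-site
  syde: SYDE1,2
  instances:
  - {protein_id: SYDE1, start: 112, end: 116, peptide: YNPIP}
  - {protein_id: SYDE2, start: 372, end: 376, peptide: YNPIP}
- motif_id: MOD_GSK3_1
  elm_class: MOD_GSK3_1
  interactor: GSK3
  consensus_text: "S/T-x-x-x-S/T GSK3 phosphorylation recognition site"
  pattern: "[ST]...[ST]"
  elm_score_printed: 2.68e-02
  pathway: Regulation of synaptic clustering
  kind: modification-site
  whitelisted: true
  syde: SYDE1,2
  instances:
  - {protein_id: SYDE1, start: 228, end: 235, peptide: GYLSDGDS}
  - {protein_id: SYDE2, start: 619, end: 626, peptide: GYLSDGDS}
sites:
- {protein_id: SYDE1, site_type: palmitoylation, start: 734, end: 734,
   peptide: C, source: SwissPalm/curated}
- {protein_id: SYDE1, site_type: NES, start: 536, end: 541,
   peptide: LRLVSS, source: NESdb/high-throughput AP-MS}
- {protein_id: SYDE1, site_type: NES, start: 713, end: 728,
   peptide: LKDFDALILDLERELS, source: NESdb/high-throughput AP-MS}
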