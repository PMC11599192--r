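# Evidence catalog for the nine canonical CD28-family receptors plus the
# chondrichthyan CD28/CTLA4 co-ortholog class.
#
# Each profile lists the degenerate consensus motifs diagnostic for the
# family (with the structural region they must fall in and whether they are
# REQUIRED across the family's full species range or SUPPORTING /
# lineage-restricted), the conserved-synteny marker genes of its locus, and
# architecture flags. Marker symbols are lower case without paralog
# suffixes. The cassette marker set shared by CD28/CTLA4/ICOS and the
# chondrichthyan co-orthologs uses the human 2q33 neighborhood symbols.
catalog_version: "1.0"
profiles:
- name: CD28
  allow_divergent_igv: no
  markers: [raph1, abi2, cyp20a1, wdr12, pard3b]
  motifs:
  - notation: "PPP"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 proline triplet, conserved from basal actinopterygians to mammals"
  - notation: "YxxxxT"
    region: TM
    weight: SUPPORTING
    lineage_note: "transmembrane dimerization motif, present in most but not all lineages"
  - notation: "[D/E/V/I]-Y-M-[N/D]-[M/I/V/T]"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "PI3K (YxxM) / GRB2-GADS (YxNx) signaling consensus; lost in cyprinids"
  notes: >-
    The proline signaling motifs PRRP and PYAP of human CD28 are not
    conserved outside mammals and are recorded here as a note only.
- name: CTLA4
  allow_divergent_igv: no
  markers: [raph1, abi2, cyp20a1, wdr12, pard3b]
  motifs:
  - notation: "[M/L/I]-[Y/F]-P-P-P-Y"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "extended CDR3 proline motif present across the family range"
  - notation: "GxG"
    region: G_STRAND
    weight: REQUIRED
    lineage_note: "di-glycine beta-bulge motif of the V-domain G strand"
  - notation: "V-[N/D]-L"
    region: E_STRAND
    weight: REQUIRED
    lineage_note: "E-strand motif; the Asn carries a structurally critical glycan in human"
  - notation: "Y-[E,G,R]-N-F"
    region: CTERM
    weight: SUPPORTING
    lineage_note: "C-terminal YxNF endocytosis motif of spotted gar and teleosts"
  notes: ""
- name: ICOS
  allow_divergent_igv: no
  markers: [raph1, abi2, cyp20a1, wdr12, pard3b]
  motifs:
  - notation: "P-[P/A/L]-P"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 proline motif, less strictly conserved than in CD28/CTLA4"
  - notation: "E-Y-M-[D/P/F]-M"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "cytoplasmic signaling consensus fully conserved from fish to human"
  - notation: "YxxxxT"
    region: TM
    weight: SUPPORTING
    lineage_note: "dimerization motif in gar, sterlet and paddlefish but not amniotes"
  - notation: "GxG"
    region: G_STRAND
    weight: SUPPORTING
    lineage_note: "G-strand GxG in turtle, gar and sterlet but not mouse and human"
  notes: ""
- name: CD28_CTLA4_CO_ORTHOLOG
  allow_divergent_igv: no
  markers: [raph1, abi2, cyp20a1, wdr12, pard3b]
  motifs:
  - notation: "P-[P/L]-P"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 proline motif of the chondrichthyan cassette genes"
  - notation: "GxG"
    region: G_STRAND
    weight: REQUIRED
    lineage_note: "G-strand GxG following the CDR3 motif, as in CTLA4"
  - notation: "YxxxxT"
    region: TM
    weight: SUPPORTING
    lineage_note: "dimerization motif generally present in the TM"
  - notation: "EYxNM"
    region: CYTOPLASMIC
    weight: SUPPORTING
    lineage_note: "generally present in genes at the third cassette position"
    cassette_position: 3
  notes: >-
    Chondrichthyan CD28/CTLA4-like sequences that cannot be resolved into
    CD28, CTLA4 or ICOS orthology; two or three copies per genome at the
    ancestral three-gene cassette. Cassette position (1/2/3) is attached as
    evidence metadata, not as separate profiles.
- name: CD28H
  allow_divergent_igv: no
  markers: [fsd1, stap2]
  motifs:
  - notation: "E-I-P"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 EIP highly conserved from sharks to mammals"
  - notation: "E-I-P-P-P"
    region: CDR3_NEIGHBORHOOD
    weight: SUPPORTING
    lineage_note: "extended EIPPP in reptiles and chondrichthyans; possibly primordial"
  - notation: "Y-[E/G/V/T/A]-N-[V/I/M/T]"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "GRB2/GADS binding consensus (YxNx) present in all sequences"
  notes: ""
- name: CD28HL1
  allow_divergent_igv: no
  markers: [man2b, kiaa0232, tcb1d14]
  motifs:
  - notation: "YxC[E/K/Q/N-polar]xxx-E-I-P"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 motif similar to CD28H; EIP not followed by P outside Chondrichthyes"
  - notation: "Y[E/D]SF"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "highly conserved cytoplasmic Y[E/D]SF, distinct from the CD28H YEDM"
  notes: >-
    The [E/K/Q/N-polar] class is encoded as the explicit residue set
    E,K,Q,N,S,T ("N-polar" read as asparagine plus polar residues).
- name: CD28HL2
  allow_divergent_igv: no
  markers: [slbp, tacc3, tmem129]
  motifs:
  - notation: "Y-x-C-[E/K/Q/N-polar]-xxx-E-I-P-[P/A/L/V]-[P/F/L]"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 motif; a PxP is present in most but not all species"
  - notation: "Y-x-N-x"
    region: CTERM
    weight: SUPPORTING
    lineage_note: "YxNx near the C terminus in almost all species"
  notes: ""
- name: CD28HL3
  allow_divergent_igv: no
  markers: [prkab1b, pla2g1b, tmem233]
  motifs:
  - notation: "YxCxxxxx[I,A,V,L]P"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 motif of the CD28HL3 set"
  - notation: "[I,V]xYxxL (X)_n VTYxxV"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "typical ITIM/ITSM pair in the cytoplasmic region"
  notes: ""
- name: CD28X
  allow_divergent_igv: no
  markers: [pudp, sts, anos1, nlgn4x, pnpla4]
  motifs:
  - notation: "YxCx_6_PPPx_4/5_GxG"
    region: CDR3_NEIGHBORHOOD
    weight: REQUIRED
    lineage_note: "CDR3 PPP with downstream GxG, reminiscent of the CTLA4 signature"
  - notation: "YxxxxT"
    region: TM
    weight: SUPPORTING
    lineage_note: "potential dimerization motif, not present in all species"
  - notation: "EYEDM"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "highly conserved cytoplasmic EYEDM, a potential PI3K recruitment site"
  notes: ""
- name: PD1
  allow_divergent_igv: yes
  markers: [pcyt1a, tctexd2, rtp, muc4, tnk2, tfrx, zdhhcl9]
  motifs:
  - notation: "[I,V]xYxxL"
    region: CYTOPLASMIC
    weight: REQUIRED
    lineage_note: "ITIM, highly conserved outside Chondrichthyes"
  - notation: "TxYxx[V/I]"
    region: CYTOPLASMIC
    weight: SUPPORTING
    lineage_note: "ITSM consensus conserved in amniotes, divergent in frog and fish"
  notes: >-
    No CDR3 consensus: the CDR3 loop has no conserved prolines, and in bony
    fish the V domain lacks the canonical framework cysteines/tryptophan,
    hence allow_divergent_igv. Marker set is the union of the
    tetrapod/bony-fish block (pcyt1a, tctexd2, rtp) and the
    tetrapod/chondrichthyan block (muc4, tnk2, tfrx, zdhhcl9).
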