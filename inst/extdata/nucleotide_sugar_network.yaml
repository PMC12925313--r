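# Curated reference network for bacterial nucleotide-sugar biosynthesis.
#
# Directed reactions run from central-carbon entry points
# (fructose-6-phosphate F6P, ribulose-5-phosphate Ru5P,
# sedoheptulose-7-phosphate S7P) to activated-sugar products. Each reaction
# is gated by KEGG Orthology gene families: `genes` is a list of
# alternatives (isoenzymes, OR), each alternative a list of families that
# must all be present (complex, AND). This transcription follows the
# standard KEGG map01250-style routes; it is curation, meant to be edited
# and extended for the organism group under study.
metabolites:
  - F6P            # fructose-6-phosphate (source)
  - Ru5P           # ribulose-5-phosphate (source)
  - S7P            # sedoheptulose-7-phosphate (source)
  - G6P            # glucose-6-phosphate
  - G1P            # glucose-1-phosphate
  - UDP-glucose
  - UDP-galactose
  - UDP-glucuronate
  - UDP-xylose
  - GlcN6P         # glucosamine-6-phosphate
  - GlcN1P         # glucosamine-1-phosphate
  - UDP-GlcNAc
  - UDP-ManNAc
  - M6P            # mannose-6-phosphate
  - M1P            # mannose-1-phosphate
  - GDP-mannose
  - GDP-4k6dMan    # GDP-4-keto-6-deoxymannose
  - GDP-fucose
  - dTDP-glucose
  - dTDP-4oxo-6dGlc
  - dTDP-4oxo-Rha
  - dTDP-rhamnose
  - ManNAc
  - Neu5Ac
  - CMP-Neu5Ac
  - H7P            # D-glycero-D-manno-heptose-7-phosphate
  - H17PP          # D-glycero-D-manno-heptose-1,7-bisphosphate
  - H1P            # D-glycero-D-manno-heptose-1-phosphate
  - ADP-heptose
sources: [F6P, Ru5P, S7P]
reactions:
  - {id: pgi,  substrate: F6P, product: G6P, genes: [[K01810]]}
  - {id: pgm,  substrate: G6P, product: G1P, genes: [[K01835], [K15778]]}
  - {id: galU, substrate: G1P, product: UDP-glucose, genes: [[K00963]]}
  - {id: galE, substrate: UDP-glucose, product: UDP-galactose,
     genes: [[K01784]]}
  - {id: ugd,  substrate: UDP-glucose, product: UDP-glucuronate,
     genes: [[K00012]]}
  - {id: uxs,  substrate: UDP-glucuronate, product: UDP-xylose,
     genes: [[K08678]]}
  - {id: glmS, substrate: F6P, product: GlcN6P, genes: [[K00820]]}
  - {id: glmM, substrate: GlcN6P, product: GlcN1P, genes: [[K03431]]}
  - {id: glmU, substrate: GlcN1P, product: UDP-GlcNAc, genes: [[K04042]]}
  - {id: wecB, substrate: UDP-GlcNAc, product: UDP-ManNAc,
     genes: [[K01791]]}
  - {id: manA, substrate: F6P, product: M6P, genes: [[K01809]]}
  - {id: manB, substrate: M6P, product: M1P, genes: [[K01840]]}
  - {id: manC, substrate: M1P, product: GDP-mannose, genes: [[K00966]]}
  - {id: gmd,  substrate: GDP-mannose, product: GDP-4k6dMan,
     genes: [[K01711]]}
  - {id: fcl,  substrate: GDP-4k6dMan, product: GDP-fucose,
     genes: [[K02377]]}
  - {id: rmlA, substrate: G1P, product: dTDP-glucose, genes: [[K00973]]}
  - {id: rmlB, substrate: dTDP-glucose, product: dTDP-4oxo-6dGlc,
     genes: [[K01710]]}
  - {id: rmlC, substrate: dTDP-4oxo-6dGlc, product: dTDP-4oxo-Rha,
     genes: [[K01790]]}
  - {id: rmlD, substrate: dTDP-4oxo-Rha, product: dTDP-rhamnose,
     genes: [[K00067]]}
  - {id: neuC, substrate: UDP-GlcNAc, product: ManNAc, genes: [[K01791]]}
  - {id: neuB, substrate: ManNAc, product: Neu5Ac, genes: [[K01654]]}
  - {id: neuA, substrate: Neu5Ac, product: CMP-Neu5Ac, genes: [[K00983]]}
  - {id: gmhA, substrate: S7P, product: H7P, genes: [[K03271]]}
  - {id: hldE-kin, substrate: H7P, product: H17PP, genes: [[K03272], [K21344]]}
  - {id: gmhB, substrate: H17PP, product: H1P, genes: [[K03273]]}
  - {id: hldE-ado, substrate: H1P, product: ADP-heptose,
     genes: [[K03272], [K21345]]}
products:
  UDP-glucose: galU
  UDP-galactose: galE
  UDP-glucuronate: ugd
  UDP-xylose: uxs
  UDP-GlcNAc: glmU
  UDP-ManNAc: wecB
  GDP-mannose: manC
  GDP-fucose: fcl
  dTDP-rhamnose: rmlD
  CMP-Neu5Ac: neuA
  ADP-heptose: hldE-ado
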