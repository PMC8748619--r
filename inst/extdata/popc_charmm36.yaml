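resname: POPC
bonds:
- site: gamma
  resonance: gamma
  C:
  - C13
  - C14
  - C15
  H:
  - - H13A
    - H13B
    - H13C
  - - H14A
    - H14B
    - H14C
  - - H15A
    - H15B
    - H15C
  neighbors: 'N'
  kind: HC
- site: beta
  resonance: beta
  C: C12
  H:
  - H12A
  - H12B
  neighbors:
  - 'N'
  - C11
  kind: HC
- site: alpha
  resonance: alpha
  C: C11
  H:
  - H11A
  - H11B
  neighbors:
  - O12
  - C12
  kind: HC
- site: g3
  resonance: g3
  C: C1
  H:
  - HA
  - HB
  neighbors:
  - O11
  - C2
  kind: HC
- site: g2
  resonance: g2
  C: C2
  H: HS
  neighbors:
  - C1
  - C3
  - O21
  kind: HC
- site: g1
  resonance: g1
  C: C3
  H:
  - HX
  - HY
  neighbors:
  - C2
  - O31
  kind: HC
- site: ole_C1
  resonance: ole_C1
  C: C21
  H: O22
  neighbors:
  - O21
  - C22
  - O22
  kind: CO
- site: pal_C1
  resonance: pal_C1
  C: C31
  H: O32
  neighbors:
  - O31
  - C32
  - O32
  kind: CO
- site: ole_C2
  resonance: ole_C2
  C: C22
  H:
  - H2R
  - H2S
  neighbors:
  - C21
  - C23
  kind: HC
- site: ole_C3
  resonance: ole_C3
  C: C23
  H:
  - H3R
  - H3S
  neighbors:
  - C22
  - C24
  kind: HC
- site: ole_C4
  resonance: chain_bulk
  C: C24
  H:
  - H4R
  - H4S
  neighbors:
  - C23
  - C25
  kind: HC
- site: ole_C5
  resonance: chain_bulk
  C: C25
  H:
  - H5R
  - H5S
  neighbors:
  - C24
  - C26
  kind: HC
- site: ole_C6
  resonance: chain_bulk
  C: C26
  H:
  - H6R
  - H6S
  neighbors:
  - C25
  - C27
  kind: HC
- site: ole_C7
  resonance: chain_bulk
  C: C27
  H:
  - H7R
  - H7S
  neighbors:
  - C26
  - C28
  kind: HC
- site: ole_C8
  resonance: ole_C8
  C: C28
  H:
  - H8R
  - H8S
  neighbors:
  - C27
  - C29
  kind: HC
- site: ole_C9
  resonance: ole_C9
  C: C29
  H: H9R
  neighbors:
  - C28
  - C210
  kind: HC
- site: ole_C10
  resonance: ole_C10
  C: C210
  H: H10R
  neighbors:
  - C29
  - C211
  kind: HC
- site: ole_C11
  resonance: ole_C11
  C: C211
  H:
  - H11R
  - H11S
  neighbors:
  - C210
  - C212
  kind: HC
- site: ole_C12
  resonance: chain_bulk
  C: C212
  H:
  - H12R
  - H12S
  neighbors:
  - C211
  - C213
  kind: HC
- site: ole_C13
  resonance: chain_bulk
  C: C213
  H:
  - H13R
  - H13S
  neighbors:
  - C212
  - C214
  kind: HC
- site: ole_C14
  resonance: chain_bulk
  C: C214
  H:
  - H14R
  - H14S
  neighbors:
  - C213
  - C215
  kind: HC
- site: ole_C15
  resonance: chain_bulk
  C: C215
  H:
  - H15R
  - H15S
  neighbors:
  - C214
  - C216
  kind: HC
- site: ole_C16
  resonance: ole_C16
  C: C216
  H:
  - H16R
  - H16S
  neighbors:
  - C215
  - C217
  kind: HC
- site: ole_C17
  resonance: ole_C17
  C: C217
  H:
  - H17R
  - H17S
  neighbors:
  - C216
  - C218
  kind: HC
- site: ole_C18
  resonance: ole_C18
  C: C218
  H:
  - H18R
  - H18S
  - H18T
  neighbors: C217
  kind: HC
- site: pal_C2
  resonance: pal_C2
  C: C32
  H:
  - H2X
  - H2Y
  neighbors:
  - C31
  - C33
  kind: HC
- site: pal_C3
  resonance: pal_C3
  C: C33
  H:
  - H3X
  - H3Y
  neighbors:
  - C32
  - C34
  kind: HC
- site: pal_C4
  resonance: chain_bulk
  C: C34
  H:
  - H4X
  - H4Y
  neighbors:
  - C33
  - C35
  kind: HC
- site: pal_C5
  resonance: chain_bulk
  C: C35
  H:
  - H5X
  - H5Y
  neighbors:
  - C34
  - C36
  kind: HC
- site: pal_C6
  resonance: chain_bulk
  C: C36
  H:
  - H6X
  - H6Y
  neighbors:
  - C35
  - C37
  kind: HC
- site: pal_C7
  resonance: chain_bulk
  C: C37
  H:
  - H7X
  - H7Y
  neighbors:
  - C36
  - C38
  kind: HC
- site: pal_C8
  resonance: chain_bulk
  C: C38
  H:
  - H8X
  - H8Y
  neighbors:
  - C37
  - C39
  kind: HC
- site: pal_C9
  resonance: chain_bulk
  C: C39
  H:
  - H9X
  - H9Y
  neighbors:
  - C38
  - C310
  kind: HC
- site: pal_C10
  resonance: chain_bulk
  C: C310
  H:
  - H10X
  - H10Y
  neighbors:
  - C39
  - C311
  kind: HC
- site: pal_C11
  resonance: chain_bulk
  C: C311
  H:
  - H11X
  - H11Y
  neighbors:
  - C310
  - C312
  kind: HC
- site: pal_C12
  resonance: chain_bulk
  C: C312
  H:
  - H12X
  - H12Y
  neighbors:
  - C311
  - C313
  kind: HC
- site: pal_C13
  resonance: chain_bulk
  C: C313
  H:
  - H13X
  - H13Y
  neighbors:
  - C312
  - C314
  kind: HC
- site: pal_C14
  resonance: pal_C14
  C: C314
  H:
  - H14X
  - H14Y
  neighbors:
  - C313
  - C315
  kind: HC
- site: pal_C15
  resonance: pal_C15
  C: C315
  H:
  - H15X
  - H15Y
  neighbors:
  - C314
  - C316
  kind: HC
- site: pal_C16
  resonance: pal_C16
  C: C316
  H:
  - H16X
  - H16Y
  - H16Z
  neighbors: C315
  kind: HC
groups:
  glycerol:
    atoms:
    - C1
    - C2
    - C3
    - O11
    - O21
    - O31
    kind: rigid_align
  palmitoyl:
    atoms:
    - C32
    - C33
    - C34
    - C35
    - C36
    - C37
    - C38
    - C39
    - C310
    - C311
    - C312
    - C313
    - C314
    - C315
    - C316
    kind: moi
  oleoyl:
    atoms:
    - C22
    - C23
    - C24
    - C25
    - C26
    - C27
    - C28
    - C29
    - C210
    - C211
    - C212
    - C213
    - C214
    - C215
    - C216
    - C217
    - C218
    kind: moi
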