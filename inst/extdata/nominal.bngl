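# Nominal AMPK-MTORC1-ULK1 autophagy/translation switch model.
# Seven molecule types, 29 interaction rules (27 unidirectional, 2
# bidirectional), mass-action rates.  Units: copies/cell and s^-1
# (bimolecular rate constants in (copies/cell)^-1 s^-1).
# AMPK carries an explicit T172 site fixed at ~P in the seed: every AMPK in
# the model is the kinase-domain-phosphorylated form (AMPK*), and the rules
# that test T172~P apply verbatim.

begin parameters
  a1      1e-3
  a2      1e-3
  a3      1e-3
  a4      1e-5
  a5      1e-5
  d1      1e-2
  d2      1e-1
  d3      1e-1
  d3max   10
  d4      1
  d5      10
  p1      10
  p2      10
  p3      10
  p4      10
  p5      1e-4
  p6      1e-6
  p7      10
  p8      10
  p9      0
  u0      1e-2
  u1      1e-3
  u2      1e-4
  MTOR_0      2e4
  RPTOR_0     2e4
  ULK1_0      1e4
  EIF4EBP1_0  1e4
  AMBRA1_0    1e4
  AMPK_star   3e4
  rapa_star   0
end parameters

begin molecule types
  rapa(mtor)
  AMPK(ulk1,ST~0~P,T172~0~P)
  MTOR(HEAT,FRB)
  RPTOR(RNC,ulk1,WD40,S792~0~P,S855_S859~0~P~PP)
  ULK1(straptor,stampk,S317~0~P,S758~0~P,S778~0~P)
  EIF4EBP1(RCR,S65_T70~0~P)
  AMBRA1(ST~0~P)
end molecule types

begin seed species
  rapa(mtor)                                      rapa_star
  AMPK(ulk1,ST~0,T172~P)                          AMPK_star
  MTOR(HEAT,FRB)                                  MTOR_0
  RPTOR(RNC,ulk1,WD40,S792~0,S855_S859~0)         RPTOR_0
  ULK1(straptor,stampk,S317~0,S758~0,S778~0)      ULK1_0
  EIF4EBP1(RCR,S65_T70~0)                         EIF4EBP1_0
  AMBRA1(ST~0)                                    AMBRA1_0
end seed species

begin reaction rules
  1:   rapa(mtor)+MTOR(HEAT,FRB) <-> rapa(mtor!1).MTOR(HEAT,FRB!1)  a1, d1
  2:   RPTOR(WD40)+MTOR(HEAT,FRB) <-> RPTOR(WD40!1).MTOR(HEAT!1,FRB)  a2, d2
  3A:  RPTOR(RNC,ulk1,S792~0,S855_S859~0)+ULK1(straptor) -> RPTOR(RNC,ulk1!1,S792~0,S855_S859~0).ULK1(straptor!1)  a3
  3B:  RPTOR(ulk1!1).ULK1(straptor!1) -> RPTOR(ulk1)+ULK1(straptor)  d3
  3C:  RPTOR(ulk1!1,S792~P,S855_S859~PP).ULK1(straptor!1) -> RPTOR(ulk1,S792~P,S855_S859~PP)+ULK1(straptor)  d3max
  4A:  RPTOR(RNC,ulk1,S792~0,S855_S859~0)+EIF4EBP1(RCR,S65_T70~0) -> RPTOR(RNC!1,ulk1,S792~0,S855_S859~0).EIF4EBP1(RCR!1,S65_T70~0)  a4
  4B:  RPTOR(RNC!1).EIF4EBP1(RCR!1) -> RPTOR(RNC)+EIF4EBP1(RCR)  d4
  5A:  AMPK(ulk1,T172~P)+ULK1(stampk,S758~0) -> AMPK(ulk1!1,T172~P).ULK1(stampk!1,S758~0)  a5
  5B:  AMPK(ulk1!1).ULK1(stampk!1) -> AMPK(ulk1)+ULK1(stampk)  d5
  6:   MTOR(HEAT!1).RPTOR(WD40!1,ulk1!2).ULK1(straptor!2,stampk,S758~0) -> MTOR(HEAT!1).RPTOR(WD40!1,ulk1!2).ULK1(straptor!2,stampk,S758~P)  p1
  7:   MTOR(HEAT!1).RPTOR(WD40!1,RNC!2).EIF4EBP1(RCR!2,S65_T70~0) -> MTOR(HEAT!1).RPTOR(WD40!1,RNC!2).EIF4EBP1(RCR!2,S65_T70~P)  p2
  8A:  RPTOR(ulk1!1,S792~0).ULK1(straptor!1,S317~P,S778~P) -> RPTOR(ulk1!1,S792~P).ULK1(straptor!1,S317~P,S778~P)  p3
  8B:  RPTOR(ulk1!1,S855_S859~0).ULK1(straptor!1,S317~P,S778~P) -> RPTOR(ulk1!1,S855_S859~P).ULK1(straptor!1,S317~P,S778~P)  2*p4
  8C:  RPTOR(ulk1!1,S855_S859~P).ULK1(straptor!1,S317~P,S778~P) -> RPTOR(ulk1!1,S855_S859~PP).ULK1(straptor!1,S317~P,S778~P)  p4
  9:   ULK1(straptor,S317~P,S778~P)+AMBRA1(ST~0) -> ULK1(straptor,S317~P,S778~P)+AMBRA1(ST~P)  p5
  10:  ULK1(straptor,S317~P,S778~P)+AMPK(ST~0) -> ULK1(straptor,S317~P,S778~P)+AMPK(ST~P)  p6
  11A: AMPK(ulk1!1,T172~P,ST~0).ULK1(stampk!1,straptor,S317~0) -> AMPK(ulk1!1,T172~P,ST~0).ULK1(stampk!1,straptor,S317~P)  p7
  11B: AMPK(ulk1!1,T172~P,ST~0).ULK1(stampk!1,S778~0) -> AMPK(ulk1!1,T172~P,ST~0).ULK1(stampk!1,S778~P)  p8
  12:  AMPK(T172~P)+RPTOR(S792~0) -> AMPK(T172~P)+RPTOR(S792~P)  p9
  13:  ULK1(S758~P) -> ULK1(S758~0)  u0
  14:  EIF4EBP1(S65_T70~P) -> EIF4EBP1(S65_T70~0)  u0
  15A: RPTOR(S792~P) -> RPTOR(S792~0)  u1
  15B: RPTOR(S855_S859~P) -> RPTOR(S855_S859~0)  u0
  15C: RPTOR(S855_S859~PP) -> RPTOR(S855_S859~P)  2*u0
  16:  AMBRA1(ST~P) -> AMBRA1(ST~0)  u0
  17:  AMPK(ST~P) -> AMPK(ST~0)  u2
  18A: ULK1(straptor,S317~P) -> ULK1(straptor,S317~0)  u0
  18B: ULK1(S778~P) -> ULK1(S778~0)  u0
  19:  RPTOR(S792~P) -> RPTOR(S792~0)  u0
end reaction rules
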