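# Temperature responses of mesophyll conductance used to standardise gm
# to 25 degC. Parameters are transcribed from the original measurement
# studies (tobacco: peaked Arrhenius; arabidopsis: weak non-peaked
# Arrhenius). Energies in J mol-1, entropy in J mol-1 K-1; the scaling
# factor is renormalised in code so that f(25 degC) = 1 exactly,
# regardless of the absolute scale of the transcription.
tobacco:
  family: peaked_arrhenius
  T_ref: 25
  params:
    c: 20.01
    Ha: 49600
    Hd: 437400
    S: 1400
arabidopsis:
  family: arrhenius
  T_ref: 25
  params:
    Ea: 20200
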