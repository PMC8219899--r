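propka3.1
--------------------------------------------------------------------------------
SUMMARY OF THIS PREDICTION
     Group      pKa  model-pKa
   ASP  308 A     6.43       3.80
   GLU  285 A     4.51       4.40
   HIS  294 A     6.10       6.50
--------------------------------------------------------------------------------
Detecting coupled residues
  ASP 308 A is coupled to GLU 285 A
    Alternative a pKa ASP 308 A     6.80
    Alternative b pKa ASP 308 A     5.90
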