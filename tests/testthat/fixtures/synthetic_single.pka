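propka3.1
--------------------------------------------------------------------------------
SUMMARY OF THIS PREDICTION
     Group      pKa  model-pKa
   ASP  308 A     4.00       3.80
--------------------------------------------------------------------------------
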