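path,peptide,label,response
structures/EVDPIGHLY.pdb,EVDPIGHLY,TRUE,high
structures/ESDPIVAQY.pdb,ESDPIVAQY,TRUE,high
structures/DECOY0001.pdb,AADPILGQY,FALSE,none
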