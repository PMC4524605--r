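((GHO:2,(LAG:1.5,(VSA:1,LRE:1,EQU:1,ACA:1)Toxicofera:0.5)Episquamata:0.5)Squamata:1,GGA:3)Root;
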