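(((A1a)A1,A2)A,((B1a)B1,B2)B,((C1a)C1,C2)C,((D1a)D1,D2)D,((E1a)E1,E2)E)ROOT;
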