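((R:1,S:1)Y:1,Z:2)X;
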