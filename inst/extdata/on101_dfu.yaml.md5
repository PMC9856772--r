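891cb02ed90a2b6825752a0282c5ae54
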