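b39d998b6db3d9325b33ae6a1f11abad
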