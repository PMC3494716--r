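position
16093
16129
16189
16192
16223
16311
16362
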