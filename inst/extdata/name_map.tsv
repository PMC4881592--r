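mirna	stem_loop
miR-92	hsa-mir-92a-1
miR106a	hsa-mir-106a
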