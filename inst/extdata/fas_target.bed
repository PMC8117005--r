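chr10	90770499	90774500	FAS_ex7_9_target
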