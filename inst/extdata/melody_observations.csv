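"outcome","outcome_label"
1,"A"
2,"B"
3,"C"
4,"D"
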