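label,count
strongly agree,186
agree,496
not agree/disagree,229
disagree,181
strong disagree,38
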