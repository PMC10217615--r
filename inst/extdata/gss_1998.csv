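label,count
strongly agree,148
agree,429
not agree/disagree,278
disagree,275
strong disagree,72
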