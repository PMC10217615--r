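label,count
strongly agree,285
agree,602
not agree/disagree,210
disagree,196
strong disagree,30
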