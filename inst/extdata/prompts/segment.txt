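Split the following ophthalmology note into discrete findings, one per
line, preserving the original order. Return only the findings.

{input}
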