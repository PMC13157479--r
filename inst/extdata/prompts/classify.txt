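Classify the following single ophthalmic finding as exactly one of
"pathological", "normal" or "negated". Return only the label.

{input}
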