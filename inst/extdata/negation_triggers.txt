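# Negation triggers (one phrase per line, matched with word boundaries,
# case-insensitive, scoped to the whole segment).
no
not
without
neither
denies
ruled out
not present
negative for
kein
keine
keinerlei
nicht
ohne
ausgeschlossen
frei von
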