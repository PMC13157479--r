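# Normal-finding markers (one phrase per line): a non-negated segment
# matching any of these is classified as a normal finding.
clear
unremarkable
normal
quiet
attached
bland
within normal limits
unauffällig
regelrecht
reizfrei
anliegend
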