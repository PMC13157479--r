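Translate the following German ophthalmology note to English, keeping
clinical terminology precise. Return only the translation.

{input}
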