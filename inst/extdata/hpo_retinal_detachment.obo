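format-version: 1.2
ontology: hp-subset

[Term]
id: HP:0000541
name: Retinal detachment
def: "Separation of the inner layers of the retina from the retinal pigment epithelium." []
synonym: "Amotio retinae" EXACT []
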