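# German -> English ophthalmic lexicon used by the rule-based
# translation backend (longest phrase wins; word-boundary matches).
Amotio retinae	retinal detachment
Netzhautablösung	retinal detachment
Wimpernverlust	Eyelash loss
Roth-Fleck	Roth spot
Zielscheibenmakulopathie	Target maculopathy
Aderhautnävus am unteren Gefäßbogen	Choroidal nevus at the inferior vascular arcade
Doppelreihige Laserherde	Double row laser burns
Rote Katarakt	Red cataract
Makulazysten	Macular cystic lesions
Drusen in atrophischen Arealen	Drusen within atrophic areas
Frische Laserherde	Fresh laser burns
Wimpernverdopplung	Double eyelashes
Hornhaut	cornea
Linse	lens
Glaskörper	vitreous
Papille	optic disc
Vorderkammer	anterior chamber
Netzhaut	retina
klar	clear
unauffällig	unremarkable
regelrecht	normal
reizfrei	quiet
anliegend	attached
kein	no
keine	no
keinerlei	no
ohne	without
nicht	not
ausgeschlossen	ruled out
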