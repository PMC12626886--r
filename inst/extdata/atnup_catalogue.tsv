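# Catalogue of currently reported A. thaliana nucleoporins used for the
# census; `group` is an annotation only and is not used in counts.
protein	group
ALADIN	core
NUP50C	basket
NUP50B	basket
NUP50A	basket
HOS1	Y-complex
NUP205	inner-ring
GP210	transmembrane
NUP35	inner-ring
NUP43	Y-complex
NUP54	channel
NUP58	channel
NUP62	channel
NUP82	cytoplasmic
NUP85	Y-complex
NUP88	cytoplasmic
NUP93A	inner-ring
NUP93B	inner-ring
NUP96	Y-complex
NUP98A	FG
NUP98B	FG
NUP107	Y-complex
NUP133	Y-complex
NUP136	basket
NUP155	inner-ring
NUP160	Y-complex
NUP214	cytoplasmic
NUA	basket
NUP188	inner-ring
NDC1	transmembrane
GLE1	cytoplasmic
RAE1	cytoplasmic
SEH1	Y-complex
SEC13A	Y-complex
SEC13B	Y-complex
CG1	cytoplasmic
GBPL3	basket
CPR5	transmembrane
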