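symbol	category
TNFSF12	druggable genome
SLC22A4	druggable genome
SPARC	druggable genome
KL	druggable genome
RELT	druggable genome
ADORA3	druggable genome
ACE	druggable genome
HMGCR	druggable genome
PCSK9	druggable genome
F2	druggable genome
NOTAREAL1	clinically actionable
NOTAREAL2	drug resistance
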