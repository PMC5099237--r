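accession	subtype
TIGR02547	I-E
TIGR02593	I-C
TIGR02590	I-A
TIGR02577	III-A
TIGR02578	III-B
TIGR01865	II-A
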