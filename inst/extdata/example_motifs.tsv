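tf_id	motif
TF01	CTTTGWW
TF02	GTCTAGAC
TF03	TGASTCA
TF04	CACGTG
TF05	TTGACWT
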