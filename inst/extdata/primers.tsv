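name	sequence	direction
gli2_F	ATGAARACMTTTCYCATC	forward
gli2_R	YAGTTRGTACCRAAGATGM	reverse
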