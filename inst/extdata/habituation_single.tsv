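speaker_id	group	object_id	token
s1	unknown	obj	buk
s1	unknown	obj	buk
s1	unknown	obj	buk
s1	unknown	obj	buk
s1	unknown	obj	buk
s1	unknown	obj	buk
s1	unknown	obj	buk
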