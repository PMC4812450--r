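class	shared	panay_private	negros_private
all	3969361	457741	251910
synonymous	19565	2150	1190
nonsyn_tolerated	10081	918	533
nonsyn_not_tolerated	3370	343	171
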