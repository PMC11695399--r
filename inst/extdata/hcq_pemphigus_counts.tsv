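cell	description	count
a	hydroxychloroquine and pemphigus	1545
b	pemphigus without hydroxychloroquine	1003
c	hydroxychloroquine without pemphigus	61993
d	neither	11375215
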