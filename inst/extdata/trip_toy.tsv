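sample	wind	humidity	temperature	class
u1	1	1	3	yes
u2	2	2	2	yes
u3	3	3	?	yes
u4	1	2	3	no
u5	?	?	3	no
u6	2	3	1	yes
u7	?	1	1	yes
u8	3	3	3	no
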