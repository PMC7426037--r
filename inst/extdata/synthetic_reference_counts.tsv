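phrase	count
people	847
time	692
way	431
world	318
work	305
life	297
day	264
thing	241
place	198
part	186
hand	173
point	121
group	118
number	96
problem	88
question	74
example	51
value	43
line	39
order	27
linear map	0
vector space	2
matrix	4
set	210
form	97
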