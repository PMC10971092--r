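the	69971
of	36412
and	28853
to	26158
a	23308
in	21341
is	10109
was	9815
cat	42
sat	18
apples	12
triangle	9
rectangle	7
marbles	5
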