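token,tag
red,JJ
green,JJ
long,JJ
new,JJ
good,JJ
tall,JJ
quickly,RB
slowly,RB
carefully,RB
almost,RB
exactly,RB
cat,NN
dog,NN
boy,NN
girl,NN
triangle,NN
run,VB
draw,VB
count,VB
buy,VB
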