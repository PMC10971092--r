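item,stem,item_type,story
item1,"Maria has 3 red apples and 5 green apples. How many apples does she have?",1,0
item2,"Draw a long line under the triangle.",0,0
item3,"A boy quickly counted 12 marbles. He gave 4 marbles to a girl. How many marbles are left?",1,1
item4,"Which rectangle shows exactly one half shaded?",1,0
item5,"The class made a picture graph of favourite animals. How many children chose the cat?",1,1
item6,"Count the triangles in the figure carefully and write the total number.",0,0
item7,"A new pencil costs 7 cents. What is the cost of 3 new pencils?",1,0
item8,"Look at the number line. What number comes next?",0,0
item9,"Ana bought 2 tall glasses of water. Each glass holds 250 millilitres. How much water is that?",1,1
item10,"Circle the shape with exactly four equal sides.",0,0
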