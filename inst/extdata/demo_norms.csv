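test,age_min,age_max,mean,sd
TMT_A,20,39,28,9
TMT_A,40,49,31,9
TMT_A,50,59,34,9
TMT_A,60,69,38,10
TMT_A,70,79,44,12
TMT_B,20,39,58,18
TMT_B,40,49,66,20
TMT_B,50,59,77,22
TMT_B,60,69,90,26
TMT_B,70,79,110,32
DST,20,39,55,10
DST,40,49,50,10
DST,50,59,46,10
DST,60,69,41,10
DST,70,79,36,10
WORDLIST_LEARNING,20,39,24,3.5
WORDLIST_LEARNING,40,49,23,3.5
WORDLIST_LEARNING,50,59,22,3.5
WORDLIST_LEARNING,60,69,21,3.5
WORDLIST_LEARNING,70,79,19,3.5
WORDLIST_RECALL,20,39,8.5,1.5
WORDLIST_RECALL,40,49,8,1.5
WORDLIST_RECALL,50,59,7.5,1.5
WORDLIST_RECALL,60,69,7,1.5
WORDLIST_RECALL,70,79,6,1.5
PEGBOARD_DOM,20,39,62,10
PEGBOARD_DOM,40,49,66,10
PEGBOARD_DOM,50,59,71,11
PEGBOARD_DOM,60,69,77,12
PEGBOARD_DOM,70,79,85,14
PEGBOARD_NONDOM,20,39,68,11
PEGBOARD_NONDOM,40,49,72,11
PEGBOARD_NONDOM,50,59,78,12
PEGBOARD_NONDOM,60,69,85,13
PEGBOARD_NONDOM,70,79,93,15
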