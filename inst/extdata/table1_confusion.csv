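call_type,High hoot,Scream,Grunt,Peep,Laughter,Low hoot,Whistle,Contest hoot,Pant grunt,Yelp,Peep yelp,Scream bark,Wieew bark,Bark,Soft bark,classification_error
High hoot,243,1,0,0,0,0,2,3,0,4,11,1,8,9,2,0.147
Scream,14,58,0,3,0,0,6,0,0,0,0,1,1,2,1,0.326
Grunt,0,0,97,5,4,8,0,0,8,2,9,0,0,0,0,0.267
Peep,9,0,11,102,0,0,2,2,2,8,14,0,0,0,1,0.325
Laughter,1,0,6,0,22,0,0,0,0,0,0,0,0,0,0,0.241
Low hoot,2,0,22,0,0,48,0,0,0,1,0,0,2,0,1,0.368
Whistle,20,6,0,4,0,0,50,3,0,2,2,0,0,2,2,0.451
Contest hoot,6,0,0,3,0,0,1,37,0,1,6,2,0,1,1,0.362
Pant grunt,0,0,6,0,0,1,0,0,36,0,10,0,0,0,0,0.321
Yelp,21,0,12,12,0,2,2,1,1,39,17,0,0,0,0,0.636
Peep yelp,21,0,16,30,0,1,3,2,4,16,58,0,0,1,5,0.631
Scream bark,16,5,0,0,0,0,3,4,0,0,0,9,0,2,1,0.775
Wieew bark,34,0,2,0,1,2,0,2,0,0,2,0,15,0,0,0.741
Bark,49,1,1,1,0,1,6,1,2,1,15,1,0,22,3,0.788
Soft bark,23,0,5,4,0,0,3,7,3,3,15,0,2,8,6,0.924
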