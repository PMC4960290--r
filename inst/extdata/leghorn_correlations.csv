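"","skull_length","skull_width","humerus","ulna","femur","tibia"
"skull_length",1,0.584,0.615,0.601,0.57,0.6
"skull_width",0.584,1,0.576,0.53,0.526,0.555
"humerus",0.615,0.576,1,0.94,0.875,0.878
"ulna",0.601,0.53,0.94,1,0.877,0.886
"femur",0.57,0.526,0.875,0.877,1,0.924
"tibia",0.6,0.555,0.878,0.886,0.924,1
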