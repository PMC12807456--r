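subject_id,t_min,glucose
S01,0,112
S01,5,118
S01,10,123
S01,15,131
S01,20,138
S01,25,142
S01,30,139
S01,35,133
S01,40,127
S01,45,121
S01,50,116
S01,55,113
S02,0,96
S02,5,98
S02,10,101
S02,15,104
S02,20,108
S02,25,111
S02,30,109
S02,35,105
S02,40,102
S02,45,99
S02,50,97
S02,55,96
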