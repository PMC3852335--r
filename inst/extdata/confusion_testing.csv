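grade,Normal,I,II,III
Normal,13,1,0,0
I,0,12,1,0
II,0,0,9,0
III,0,0,0,3
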