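grade,Normal,I,II,III
Normal,29,0,0,0
I,0,26,0,0
II,0,0,17,0
III,0,0,0,7
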