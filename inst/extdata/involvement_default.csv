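label,hemisphere,grade
A,Left,-
B,Left,-
C_Pass2,Left,-
C_Pass1,Left,-
D,Left,+
E,Left,++
A,Right,+
B,Right,+
C_Pass2,Right,++
C_Pass1,Right,++
D,Right,+++
E,Right,+++
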