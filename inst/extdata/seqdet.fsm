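# Two-symbol sequence detector: the cue CA arms detection of (L, R),
# the cue CB arms detection of (R, L); the reset symbol x returns every
# state to Idle. The second symbol of an armed sequence is a detection.
initial,Idle
reset,x
Idle,CA,A0
Idle,CB,B0
A0,L,A1
A1,R,Idle,detect
B0,R,B1
B1,L,Idle,detect
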