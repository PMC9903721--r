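>SYNRE1.1 synthetic_RE1_like
A [   4   8   4  75   4   8  60   4  15  25  25   4   8  92  15  92   8  25   4  30   8 ]
C [   2   4  92  15   2  85  25  92  75  25  25   2   4   4  75   4   4  60   2  50  85 ]
G [   2   3   2   6  92   4  10   2   6  25  25  92  85   2   6   2  85  10  92  12   4 ]
T [  92  85   2   4   2   3   5   2   4  25  25   2   3   2   4   2   3   5   2   8   3 ]
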