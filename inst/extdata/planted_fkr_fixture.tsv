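A1	A2
A1	A3
A1	A4
A1	B1
A1	C1
A2	A3
A4	A5
A4	A6
A5	A6
B1	B2
B1	B3
B1	B4
B1	C1
B2	B3
B2	B5
B4	B5
B4	B6
B5	B6
C1	C2
C1	C3
C1	C4
C1	C5
C1	D1
C2	C3
C2	C4
C2	C5
C3	C4
C3	C5
C4	C5
D1	D3
D1	D4
D1	D5
D3	D2
D4	D2
D5	D2
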