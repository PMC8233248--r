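# seed: 1
# method: pg42-line-collapse
# symbol-to-level mapping: level = symbol + 1 (domain columns printed as levels 1-4)
# OA(32, 8, 4, 2): 32 runs, 8 four-level factors, strength 2 (verified exhaustively)
# within every block each domain column shows all 4 levels, each exactly 2 times
OCC,CTL,SELF,SAFE,SOC,STS,ENC,block
1,1,1,1,1,1,1,0
1,2,4,2,4,2,1,2
3,1,3,2,3,3,4,2
3,2,2,1,2,4,4,0
3,4,2,3,3,2,1,1
3,3,3,4,2,1,1,3
1,4,4,4,1,4,4,3
1,3,1,3,4,3,4,1
2,3,2,1,1,2,3,2
2,4,3,2,4,1,3,0
4,3,4,2,3,4,2,0
4,4,1,1,2,3,2,2
4,2,1,3,3,1,3,3
4,1,4,4,2,2,3,1
2,2,3,4,1,3,2,1
2,1,2,3,4,4,2,3
1,2,2,2,2,1,2,1
1,1,3,1,3,2,2,3
3,2,4,1,4,3,3,3
3,1,1,2,1,4,3,1
3,3,1,4,4,2,2,0
3,4,4,3,1,1,2,2
1,3,3,3,2,4,3,2
1,4,2,4,3,3,3,0
2,4,1,2,2,2,4,3
2,3,4,1,3,1,4,1
4,4,3,1,4,4,1,1
4,3,2,2,1,3,1,3
4,1,2,4,4,1,4,2
4,2,3,3,1,2,4,0
2,1,4,3,2,3,1,0
2,2,1,4,3,4,1,2
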