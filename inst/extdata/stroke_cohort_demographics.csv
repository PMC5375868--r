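no,sex,height_cm,weight_kg,paretic_side,age_years,onset_days,fmue_score,brunnstrom_stage
1,Male,175,71,Left,72,40,50,4
2,Female,159,48,Right,52,33,58,5
3,Male,181,81,Right,50,11,59,5
4,Male,162,65,Right,58,21,40,4
5,Female,173,66,Right,53,366,37,4
6,Male,176,75,Right,30,457,25,4
7,Male,168,68,Right,61,68,48,4
8,Female,162,49,Left,75,48,40,5
9,Male,176,71,Left,46,49,41,3
10,Male,170,68,Left,69,10,10,3
11,Female,165,55,Left,50,36,21,3
12,Female,158,49,Left,50,51,48,5
13,Male,175,72,Right,51,78,24,3
14,Female,155,45,Right,81,81,51,5
15,Male,178,72,Left,44,225,38,3
16,Female,163,66,Left,51,584,35,4
17,Male,169,73,Left,59,40,57,5
18,Male,175,72,Left,43,71,45,4
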