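group,cluster,value
1,p1_1,3
1,p1_1,2
1,p1_2,2
1,p1_2,3
1,p1_3,2
1,p1_3,2
1,p1_4,3
1,p1_4,3
1,p1_5,3
1,p1_5,3
1,p1_6,3
1,p1_6,3
1,p1_7,1
1,p1_7,1
1,p1_8,2
1,p1_8,2
1,p1_9,2
1,p1_9,1
1,p1_10,1
1,p1_10,2
1,p1_11,2
1,p1_11,1
1,p1_12,2
1,p1_12,3
2,p2_1,3
2,p2_1,2
2,p2_2,1
2,p2_2,1
2,p2_3,2
2,p2_3,1
2,p2_4,2
2,p2_4,2
2,p2_5,2
2,p2_5,2
2,p2_6,2
2,p2_6,1
2,p2_7,1
2,p2_7,1
2,p2_8,1
2,p2_8,1
2,p2_9,2
2,p2_9,1
3,p3_1,2
3,p3_1,2
3,p3_2,1
3,p3_2,2
3,p3_3,1
3,p3_3,2
3,p3_4,2
3,p3_4,2
3,p3_5,2
3,p3_5,1
3,p3_6,3
3,p3_6,3
3,p3_7,2
3,p3_7,2
3,p3_8,2
3,p3_8,2
3,p3_9,1
3,p3_9,1
3,p3_10,2
3,p3_10,2
3,p3_11,2
3,p3_11,3
3,p3_12,1
3,p3_12,2
3,p3_13,2
3,p3_13,3
3,p3_14,3
3,p3_14,3
3,p3_15,1
3,p3_15,1
3,p3_16,2
3,p3_16,1
3,p3_17,1
3,p3_17,2
3,p3_18,2
3,p3_18,2
3,p3_19,1
3,p3_19,1
3,p3_20,3
3,p3_20,3
3,p3_21,2
3,p3_21,2
4,p4_1,1
4,p4_1,2
4,p4_2,2
4,p4_2,2
4,p4_3,3
4,p4_3,3
4,p4_4,3
4,p4_4,2
4,p4_5,2
4,p4_5,3
4,p4_6,1
4,p4_6,1
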