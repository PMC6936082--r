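age_band,persons
0-4,1282357
5-9,1351664
10-14,1353177
15-19,1352745
20-24,1302412
25-29,1407081
30-34,1466615
35-39,1492204
40-44,1479257
45-49,1358594
50-54,1300777
55-59,1008799
60-64,822024
65-69,682513
70-74,638380
75-79,519356
80-84,330050
85+,265235
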