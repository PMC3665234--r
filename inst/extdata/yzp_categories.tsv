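id	category
1	III
2	III
3	III
4	III
5	III
6	III
7	II
8	II
9	III
10	III
11	II
12	II
13	II
14	II
15	I
16	III
17	II
18	II
19	II
20	II
21	I
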