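"song_id","label","group"
1,"r1","relaxing"
2,"r2","relaxing"
3,"r3","relaxing"
4,"r4","relaxing"
5,"r5","relaxing"
6,"r6","relaxing"
7,"r7","relaxing"
8,"r8","relaxing"
9,"r9","relaxing"
10,"r10","relaxing"
11,"","none"
12,"","none"
13,"","none"
14,"","none"
15,"","none"
16,"","none"
17,"","none"
18,"","none"
19,"","none"
20,"","none"
21,"","none"
22,"","none"
23,"","none"
24,"","none"
25,"","none"
26,"","none"
27,"","none"
28,"","none"
29,"","none"
30,"","none"
31,"","none"
32,"","none"
33,"","none"
34,"","none"
35,"","none"
36,"","none"
37,"","none"
38,"","none"
39,"","none"
40,"","none"
41,"","none"
42,"","none"
43,"a10","activating"
44,"a9","activating"
45,"a8","activating"
46,"a7","activating"
47,"a6","activating"
48,"a5","activating"
49,"a4","activating"
50,"a3","activating"
51,"a2","activating"
52,"a1","activating"
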