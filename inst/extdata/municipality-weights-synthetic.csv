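municipality,department,weight
05001,05,2427
05088,05,495
05360,05,267
08001,08,1206
08758,08,666
11001,11,7413
13001,13,973
15001,15,172
17001,17,400
18001,18,168
19001,19,270
20001,20,490
23001,23,460
25307,25,107
25754,25,660
27001,27,130
41001,41,357
44001,44,188
47001,47,499
50001,50,531
52001,52,392
54001,54,711
63001,63,295
66001,66,467
68001,68,581
70001,70,277
73001,73,529
76001,76,2228
76520,76,349
85001,85,151
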