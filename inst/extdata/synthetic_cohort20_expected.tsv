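sample	Rule1	Rule2	Rule3	Rule4	Rule5	Rule6	Rule7	Rule8	Rule9	Rule10	Rule11	Rule12	Rule13	Rule14	Rule15	Y
1	0	0	0	0	0	0	1	0	1	1	1	0	1	0	0	2.1374999999999993
2	0	0	0	0	1	0	0	0	1	1	1	0	0	0	0	1.0070999999999999
3	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-0.32650000000000001
4	0	0	0	0	0	0	1	0	1	1	0	0	1	1	1	2.6440000000000001
5	0	0	0	0	1	1	1	0	0	0	1	0	0	0	1	1.0932000000000002
6	1	0	0	1	0	0	0	0	0	0	0	0	0	0	0	-1.3716999999999999
7	0	0	0	0	1	0	1	0	0	0	0	0	1	1	0	0.87539999999999996
8	1	0	0	1	0	0	0	0	0	0	0	0	0	0	0	-1.3716999999999999
9	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	-1.097
10	0	0	0	0	1	0	1	0	1	0	1	0	1	1	0	1.8648999999999998
11	0	0	0	1	0	0	0	0	0	0	0	0	0	1	0	-0.022300000000000042
12	0	0	0	0	0	0	1	0	0	0	0	0	0	1	1	1.0848
13	0	0	0	0	1	0	1	0	1	1	0	0	1	0	1	1.8114000000000001
14	1	0	0	0	0	0	0	0	0	0	0	0	0	0	1	-0.70789999999999997
15	1	0	0	0	0	0	0	1	0	0	0	0	0	0	0	-1.4839
16	0	0	0	0	0	0	1	0	0	1	0	0	0	0	1	1.1037000000000001
17	0	0	0	0	1	0	1	0	0	0	1	0	1	1	1	1.7260000000000002
18	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0	-0.0013000000000000234
19	1	0	0	0	0	0	0	0	0	0	1	0	0	1	0	-0.056599999999999984
20	0	0	0	0	0	1	0	0	0	0	0	0	0	0	1	0.44209999999999994
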