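y
30
-44
23
31
26
27
23
28
30
23
26
29
32
33
27
30
26
21
28
24
32
30
28
24
34
29
29
28
26
25
27
30
27
33
23
29
36
28
34
28
24
31
31
30
31
29
32
30
30
33
21
23
31
-2
27
30
24
32
32
29
27
30
30
24
26
24
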