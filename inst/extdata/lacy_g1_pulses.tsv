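pulse
7
27
43
61
74
82
89
101
122
136
153
166
174
191
205
220
242
257
268
290
310
323
341
359
374
393
404
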