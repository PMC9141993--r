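strength,gauge_mm
43.93,10
50.16,10
101.15,10
108.94,10
123.06,10
141.38,10
151.48,10
163.4,10
177.25,10
183.16,10
212.13,10
257.44,10
262.9,10
291.27,10
303.9,10
323.83,10
353.24,10
376.42,10
383.43,10
422.11,10
506.6,10
530.55,10
590.48,10
637.66,10
671.49,10
693.73,10
700.74,10
704.66,10
727.23,10
778.17,10
36.75,20
45.58,20
48.01,20
71.46,20
83.55,20
99.72,20
113.85,20
116.99,20
119.86,20
145.96,20
166.49,20
187.13,20
187.85,20
200.16,20
244.53,20
284.64,20
350.7,20
375.81,20
419.02,20
456.6,20
547.44,20
578.62,20
581.6,20
585.57,20
594.29,20
662.66,20
688.16,20
707.36,20
756.7,20
765.14,20
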