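>group_ii_ref_1
TFALIVTRHEFPWVRDKWFQFSCIDALMRIEEVPFECCMTVGFCYDCGLIAATHEPLKLY
KMDSTQFCVTVFKPDDWALVPWSTNKPWWGAPSIKAMLLAWTQQRGRMFSTTVCGGGYRK
LNKYCCMQSCLFLTTKLQQAFCPMYTYYYMTKRNTWATNWISPSWNAWFRGSIHKKMVRR
YSAGCKEPFMMCGANSTMYC
>group_ii_ref_2
TFAVEVTRHEFQYVRDKWFPFYCIDALMRIEEVPFECCSTVGFCYDCGPIFPTHEPLKLY
KMDSFQFCVTVFQPIDWHLVPWSTNKMWWGDPSFKAGLLAWTQQRGRMFSTTVCGGDYNY
LNKYCCMQCCLFLVTKDTRAFDLMYTYYYMTKCPTWAINCISDSWNAWFGGSIHKKMVRR
YSAGCKEPFMVCGANSTMYC
>group_ii_ref_3
TFAREVTRHHFQYVRDRWFPFYCIDACMRIEEVPFECCDTVGFCYDCGLIFAYHLPLKLY
KMDSFQFCITVFQPIDWHLVPWSTNQMWWGAPSFKAMLNRWTQQRGGMFSTTVCAYGYRK
LNKYCCMQCCLFLTTKDQQAFDPMYTYYIMTKCPTWATNCISDSWNAWFRQSIHKKMVRR
YSAGNHEPFMVPGANSKMYC
>group_ii_ref_4
TFALESTRHEEQYVRDKWFPFYCIVALMRIERVPFECCDTVQFCYDCGLYFATHEPFKHY
KMDSFQFCVTVFQPIDWHLVPWSTNKMWWNAPSFKAMLLAWTQKRGRNFSTTVPGGGYRK
LNKYCCMQFDLFLTTKTQQAFVWMYTYYYMTKCPCWATNEIKDSWNAWFRGSRHKKMQRR
YSAGCKEPFMVCGACSTMYC
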