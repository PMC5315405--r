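# Generic-number ranges of the transmembrane helical bundle used as the
# default position whitelist for cross-receptor aggregation. Note that the
# TM7 ranges skip position 7x44.
1x36-1x56
2x40-2x63
3x24-3x54
4x42-4x61
5x38-5x60
6x34-6x57
7x36-7x43
7x45-7x55
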