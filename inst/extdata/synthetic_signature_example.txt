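# Synthetic example gene signature (not a published list).
# Format: one gene symbol per line; a leading "-" marks a gene that
# contributes negatively to the score.
G0001
G0042
G0107
G0256
G0311
-G0499
-G0133
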