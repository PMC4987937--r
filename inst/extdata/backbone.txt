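# Invariant S. pyogenes sgRNA scaffold (tracrRNA-fused), DNA alphabet.
# Used for guide-vs-scaffold stem counting; replace with any scaffold
# your expression system uses (one sequence line, # lines ignored).
GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC
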