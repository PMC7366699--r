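mlocarna: synthetic example output for parser tests

Perform progressive alignment ...

Score: -1234

seqA             GGGAAA-CCC
seqB             GGG-AAUCCC
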