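# Shared alphabet constants (defined first in collation order).

.DNA_ALPHABET <- c("A", "C", "G", "T")

.CODE <- setNames(0:3, .DNA_ALPHABET)
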