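# Locale-independent (C collation) string ordering: serialized sets,
# tie-breaks and batch order must not depend on LC_COLLATE, or runs
# would not reproduce across machines.
sort_c <- function(x) sort(x, method = "radix")
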