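# report every failure rather than stopping at the default cap, so the
# whole suite always runs
options(testthat.max_fails = 1000L)
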