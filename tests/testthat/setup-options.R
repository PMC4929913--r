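# The acceptance tests assert every reported quantity individually and some
# are known not to reproduce (see the package documentation); keep the
# reporter from stopping early so the whole suite always runs.
options(testthat.progress.max_fails = Inf)
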