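# extdata

`deposited/` (not shipped) is the documented drop-in location for the
~266 deposited GenBank flat-file records of the three frog species'
AMP precursor cDNAs. When files matching `*.gb`, `*.genbank` or `*.txt`
are placed there before installation, the acceptance suite reproduces the
published correlation, diversity and descriptor values from them via
`read_genbank_flat()`; without them those checks report the records as
unavailable. Everything else in the package runs on simulated data and
needs no external files.
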