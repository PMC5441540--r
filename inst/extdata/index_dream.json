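{"intercept":27.82,"coefficients":{"LCC":-0.32,"LSC":-0.012},"provenance":"fixed","fit_stats":{},"source_reports":"dream"}
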