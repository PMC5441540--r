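{"intercept":93.91,"coefficients":{"E":-3.08,"LSC":0.21},"provenance":"fixed","fit_stats":{},"source_reports":"dream"}
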