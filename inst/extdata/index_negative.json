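{"intercept":31.43,"coefficients":{"LCC":-0.3,"LSC":0.08,"LSCz":-2.12},"provenance":"fixed","fit_stats":{},"source_reports":"image_negative"}
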