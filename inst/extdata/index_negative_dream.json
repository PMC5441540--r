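{"intercept":30.78,"coefficients":{"LSC_negative":0.015,"LSCz_negative":-2.33,"LCC_dream":-0.2},"provenance":"fixed","fit_stats":{},"source_reports":["image_negative","dream"]}
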